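#' Transport (reduced) scattering coefficient
#'
#' In the diffuse regime the scattering coefficient and the anisotropy factor
#' act on photon propagation only through their combination
#' \eqn{\mu_s' = \mu_s (1 - g)}. `transport_scattering()` applies the forward
#' relation; `mus_from_musp()` inverts it, which is what the Monte Carlo engine
#' needs since it samples free paths from \eqn{\mu_s}.
#'
#' @param mus scattering coefficient (1/cm), non-negative.
#' @param musp transport scattering coefficient (1/cm), non-negative.
#' @param g anisotropy factor (mean cosine of the single-scattering deflection
#'   angle), `0 <= g < 1`.
#' @return numeric vector of coefficients (1/cm).
#' @examples
#' transport_scattering(100, 0.9) # 10
#' mus_from_musp(10, 0.9)         # 100
#' @export
transport_scattering <- function(mus, g) {
  check_anisotropy(g)
  stopifnot(all(mus >= 0))
  mus * (1 - g)
}

#' @rdname transport_scattering
#' @export
mus_from_musp <- function(musp, g) {
  check_anisotropy(g)
  stopifnot(all(musp >= 0))
  musp / (1 - g)
}

check_anisotropy <- function(g) {
  if (any(!is.finite(g)) || any(g < 0) || any(g >= 1)) {
    stop("anisotropy factor g must satisfy 0 <= g < 1", call. = FALSE)
  }
  invisible(g)
}

#' Scattering power law
#'
#' Wavelength dependence of the transport scattering coefficient is modeled as
#' an inverse power law \eqn{\mu_s'(\lambda) = A \lambda^{-K}} with the
#' wavelength in nanometers, so `A` carries units of
#' \eqn{\mathrm{cm^{-1} nm^{K}}}.
#'
#' @param A amplitude (1/cm * nm^K), positive.
#' @param K scattering power (dimensionless), typically 0.2 to 3 for soft
#'   tissue.
#' @param wavelengths wavelengths in nm, positive.
#' @return \eqn{\mu_s'} spectrum (1/cm), one value per wavelength.
#' @export
musp_powerlaw <- function(A, K, wavelengths) {
  stopifnot(A > 0, all(wavelengths > 0))
  A * wavelengths^(-K)
}

# ---- chromophore library ---------------------------------------------------

#' Load the packaged chromophore spectra
#'
#' Returns a table of chromophore optical spectra on a 1-nm grid over
#' 650--1050 nm: molar extinction coefficients of oxy- and deoxy-hemoglobin
#' (1/(cm M)), absorption coefficients of 100% (v/v) water, collagen, and
#' melanin (1/cm), and fixed absorption / transport scattering spectra of
#' cerebrospinal fluid (1/cm). The packaged file is a synthetic emulation of
#' the standard published tabulations, built from anchor points at reference
#' wavelengths and interpolated to 1 nm (see
#' `inst/extdata/chromophores_synthetic.tsv`); supply `path` to use your own
#' tabulation with the same column layout.
#'
#' Unit contract: extinction coefficients pair with total hemoglobin
#' concentration in molar units (M); the 100%-chromophore absorption spectra
#' pair with dimensionless volume fractions.
#'
#' @param path optional path to a TSV with columns `wavelength_nm`, `eps_HbO`,
#'   `eps_Hb`, `mua_water`, `mua_collagen`, `mua_melanin`, `mua_CSF`,
#'   `musp_CSF`.
#' @return a tibble with class `chromophore_library`.
#' @export
chromophore_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chromophores_synthetic.tsv",
                        package = "headfit", mustWork = TRUE)
  }
  lib <- tibble::as_tibble(utils::read.delim(path, comment.char = "#"))
  validate_chromophore_library(lib)
}

validate_chromophore_library <- function(lib) {
  required <- c("wavelength_nm", "eps_HbO", "eps_Hb", "mua_water",
                "mua_collagen", "mua_melanin", "mua_CSF", "musp_CSF")
  missing <- setdiff(required, names(lib))
  if (length(missing)) {
    stop("chromophore library lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wl <- lib$wavelength_nm
  if (any(diff(wl) <= 0)) stop("wavelength grid must be strictly increasing", call. = FALSE)
  spectra <- lib[setdiff(required, "wavelength_nm")]
  if (any(as.matrix(spectra) <= 0)) {
    stop("all chromophore spectra must be strictly positive", call. = FALSE)
  }
  if (all(lib$eps_HbO == lib$eps_Hb)) {
    stop("eps_HbO and eps_Hb are identical everywhere: no hemoglobin contrast",
         call. = FALSE)
  }
  class(lib) <- c("chromophore_library", class(lib))
  lib
}

#' Interpolate library spectra at requested wavelengths
#'
#' Linear interpolation on the library grid. Wavelengths outside the grid
#' support are an error; the library is never extrapolated.
#'
#' @param lib a [chromophore_library()].
#' @param wavelengths nm.
#' @param columns which spectra to return (default: all).
#' @return tibble with `wavelength_nm` plus the requested columns.
#' @export
interp_chromophores <- function(lib, wavelengths, columns = NULL) {
  wl <- lib$wavelength_nm
  if (any(wavelengths < min(wl)) || any(wavelengths > max(wl))) {
    stop(sprintf("requested wavelengths outside library support [%g, %g] nm",
                 min(wl), max(wl)), call. = FALSE)
  }
  if (is.null(columns)) columns <- setdiff(names(lib), "wavelength_nm")
  out <- purrr::map(columns, function(cn) {
    stats::approx(wl, lib[[cn]], xout = wavelengths)$y
  })
  names(out) <- columns
  tibble::as_tibble(c(list(wavelength_nm = wavelengths), out))
}

#' Tissue absorption from chromophore composition
#'
#' Builds the absorption spectrum of one tissue compartment from its
#' hemoglobin state and fixed chromophore volume fractions:
#' \deqn{\mu_a(\lambda) = 2.303\,[\varepsilon_{HbO}(\lambda)\,StO_2 +
#'   \varepsilon_{Hb}(\lambda)\,(1-StO_2)]\,tHB +
#'   \sum_i \mu_{a,i}(\lambda)\,C_i,}
#' where `tHB` is total hemoglobin concentration (M), `StO2` the tissue oxygen
#' saturation, and the sum runs over non-hemoglobin absorbers (water,
#' collagen, melanin) with volume fractions `C_i`.
#'
#' @param tHB total hemoglobin concentration (M), `>= 0`.
#' @param StO2 tissue oxygen saturation, in `[0, 1]`.
#' @param fractions named numeric vector of volume fractions; recognized names
#'   are `water`, `collagen`, `melanin`. Missing names mean zero.
#' @param lib a [chromophore_library()].
#' @param wavelengths nm, inside the library support.
#' @return \eqn{\mu_a} spectrum (1/cm).
#' @export
mua_from_chromophores <- function(tHB, StO2, fractions = c(), lib, wavelengths) {
  stopifnot(tHB >= 0, StO2 >= 0, StO2 <= 1)
  sp <- interp_chromophores(lib, wavelengths)
  mua <- 2.303 * (sp$eps_HbO * StO2 + sp$eps_Hb * (1 - StO2)) * tHB
  frac_cols <- c(water = "mua_water", collagen = "mua_collagen",
                 melanin = "mua_melanin")
  unknown <- setdiff(names(fractions), names(frac_cols))
  if (length(unknown)) stop("unknown chromophores: ", paste(unknown, collapse = ", "))
  for (nm in names(fractions)) {
    mua <- mua + sp[[frac_cols[[nm]]]] * fractions[[nm]]
  }
  mua
}

# ---- tissue parameters and OP ranges ---------------------------------------

#' Tunable tissue parameters of the head compartments
#'
#' The inverse problem is parameterized per compartment by total hemoglobin
#' concentration `tHB` (M), oxygen saturation `StO2`, the scattering power-law
#' coefficients `A`, `K`, and (scalp only) a melanin volume fraction. Water
#' and collagen fractions are fixed: scalp carries 75% water and 2% collagen,
#' gray matter 75% water. CSF optical properties are fixed library spectra and
#' white matter is coupled to gray matter, so neither has free parameters.
#'
#' @param scalp,skull,gm named lists overriding the defaults below.
#' @return object of class `tissue_params`.
#' @examples
#' p <- tissue_params(gm = list(tHB = 80e-6))
#' p$gm$tHB
#' @export
tissue_params <- function(scalp = list(), skull = list(), gm = list()) {
  defaults <- list(
    scalp = list(tHB = 60e-6, StO2 = 0.70, Cmelanin = 0.001, A = 4.6e4, K = 1.2),
    skull = list(tHB = 40e-6, StO2 = 0.65, A = 3.4e3, K = 0.8),
    gm    = list(tHB = 70e-6, StO2 = 0.65, A = 7.2e3, K = 1.0)
  )
  p <- defaults
  for (tis in c("scalp", "skull", "gm")) {
    ov <- get(tis)
    bad <- setdiff(names(ov), names(p[[tis]]))
    if (length(bad)) stop(sprintf("unknown %s parameter(s): %s", tis,
                                  paste(bad, collapse = ", ")))
    p[[tis]][names(ov)] <- ov
  }
  for (tis in names(p)) {
    stopifnot(p[[tis]]$tHB > 0, p[[tis]]$StO2 >= 0, p[[tis]]$StO2 <= 1,
              p[[tis]]$A > 0)
  }
  p$fixed_fractions <- list(
    scalp = c(water = 0.75, collagen = 0.02),
    skull = c(),
    gm = c(water = 0.75)
  )
  structure(p, class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("Tissue parameters (tHB in M; A in 1/cm*nm^K)\n")
  for (tis in c("scalp", "skull", "gm")) {
    cat(sprintf("  %-5s %s\n", tis,
                paste(names(x[[tis]]), signif(unlist(x[[tis]]), 4),
                      sep = "=", collapse = "  ")))
  }
  invisible(x)
}

#' Allowed optical-property ranges per compartment
#'
#' Returns the per-compartment bounds on \eqn{\mu_a} and \eqn{\mu_s'} (1/cm)
#' together with refractive index and anisotropy, used both to constrain the
#' inverse fit and to bound the lookup-table grid. The outer medium matches
#' the fiber index (1.457); all tissues share n = 1.4 and g = 0.9; sinus air
#' pockets are transparent with n = 1. CSF and sinus rows are fixed, never
#' fitted.
#'
#' @return tibble with one row per compartment.
#' @export
op_ranges <- function() {
  tibble::tribble(
    ~compartment, ~mua_min, ~mua_max, ~musp_min, ~musp_max, ~n,    ~g,  ~fitted,
    "outer",      0,        0,        0,         0,         1.457, NA,  FALSE,
    "scalp",      0.1,      0.6,      5,         35,        1.4,   0.9, TRUE,
    "skull",      0.05,     0.45,     5,         35,        1.4,   0.9, TRUE,
    "csf",        0.015,    0.1,      1,         3.7,       1.4,   0.9, FALSE,
    "gm",         0.05,     0.5,      5,         35,        1.4,   0.9, TRUE,
    "wm",         0.025,    0.25,     15,        105,       1.4,   0.9, FALSE,
    "sinus",      0,        0,        0,         0,         1,     NA,  FALSE
  )
}

#' Compartment optical-property spectra from tissue parameters
#'
#' Evaluates the per-compartment \eqn{\mu_a(\lambda)} and
#' \eqn{\mu_s'(\lambda)} at the requested wavelengths: scalp, skull, and gray
#' matter from the chromophore and power-law models; CSF copied from the fixed
#' library spectra; white matter coupled to gray matter
#' (\eqn{\mu_{a,WM} = \mu_{a,GM}/2}, \eqn{\mu_{s,WM}' = 3 \mu_{s,GM}'});
#' sinus transparent. Out-of-range values are not an error: they are collected
#' into a violation report (attribute `"violations"`) that the fitter uses as
#' its nonlinear constraint.
#'
#' @param params a [tissue_params()].
#' @param lib a [chromophore_library()].
#' @param wavelengths nm.
#' @param ranges an [op_ranges()] table.
#' @return tibble (wavelength_nm, compartment, mua, musp, mus, g, n) with a
#'   `violations` attribute (tibble, zero rows when all OPs are in range).
#' @export
params_to_op_spectra <- function(params, lib, wavelengths, ranges = op_ranges()) {
  stopifnot(inherits(params, "tissue_params"))
  nl <- length(wavelengths)
  sp_csf <- interp_chromophores(lib, wavelengths, c("mua_CSF", "musp_CSF"))

  per_tissue <- function(tis) {
    tibble::tibble(
      wavelength_nm = wavelengths,
      compartment = tis,
      mua = mua_from_chromophores(params[[tis]]$tHB, params[[tis]]$StO2,
                                  fractions_of(params, tis), lib, wavelengths),
      musp = musp_powerlaw(params[[tis]]$A, params[[tis]]$K, wavelengths)
    )
  }
  scalp <- per_tissue("scalp"); skull <- per_tissue("skull"); gm <- per_tissue("gm")
  csf <- tibble::tibble(wavelength_nm = wavelengths, compartment = "csf",
                        mua = sp_csf$mua_CSF, musp = sp_csf$musp_CSF)
  wm <- tibble::tibble(wavelength_nm = wavelengths, compartment = "wm",
                       mua = gm$mua / 2, musp = 3 * gm$musp)
  sinus <- tibble::tibble(wavelength_nm = wavelengths, compartment = "sinus",
                          mua = 0, musp = 0)
  out <- dplyr::bind_rows(scalp, skull, csf, gm, wm, sinus)
  out <- dplyr::left_join(out, ranges[c("compartment", "n", "g")],
                          by = "compartment")
  out$mus <- ifelse(!is.na(out$g) & out$g < 1, out$musp / (1 - out$g), out$musp)

  viol <- op_violations(out, ranges)
  attr(out, "violations") <- viol
  out
}

fractions_of <- function(params, tissue) {
  fr <- params$fixed_fractions[[tissue]]
  if (tissue == "scalp") fr <- c(fr, melanin = params$scalp$Cmelanin)
  fr
}

#' Out-of-range report for an OP spectra table
#'
#' @param op_spectra output of [params_to_op_spectra()].
#' @param ranges an [op_ranges()] table.
#' @return tibble (wavelength_nm, compartment, quantity, value, lo, hi).
#' @export
op_violations <- function(op_spectra, ranges = op_ranges()) {
  x <- dplyr::left_join(op_spectra, ranges, by = "compartment",
                        suffix = c("", ".rng"))
  longer <- dplyr::bind_rows(
    dplyr::transmute(x, .data$wavelength_nm, .data$compartment,
                     quantity = "mua", value = .data$mua,
                     lo = .data$mua_min, hi = .data$mua_max),
    dplyr::transmute(x, .data$wavelength_nm, .data$compartment,
                     quantity = "musp", value = .data$musp,
                     lo = .data$musp_min, hi = .data$musp_max)
  )
  dplyr::filter(longer, .data$value < .data$lo - 1e-12 |
                        .data$value > .data$hi + 1e-12)
}

#' Free optical properties at one wavelength
#'
#' Extracts the fit's optical-property vector -- \eqn{\mu_a} and
#' \eqn{\mu_s'} of the four major compartments (scalp, skull, CSF, gray
#' matter) -- from an OP spectra table at one wavelength. CSF entries are
#' fixed values carried along so the forward model sees a complete input.
#'
#' @param op_spectra output of [params_to_op_spectra()].
#' @param wavelength one wavelength present in the table.
#' @param compartments compartments to extract, in order.
#' @return named numeric vector `mua_<c>`, `musp_<c>` for each compartment.
#' @export
op_vector <- function(op_spectra, wavelength,
                      compartments = c("scalp", "skull", "csf", "gm")) {
  row <- op_spectra[op_spectra$wavelength_nm == wavelength &
                    op_spectra$compartment %in% compartments, ]
  if (nrow(row) != length(compartments)) {
    stop("wavelength not present in the OP spectra table", call. = FALSE)
  }
  row <- row[match(compartments, row$compartment), ]
  stats::setNames(c(row$mua, row$musp),
                  c(paste0("mua_", compartments), paste0("musp_", compartments)))
}
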