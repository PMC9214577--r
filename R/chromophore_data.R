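# Synthetic chromophore tables. The packaged TSV is generated by
# build_chromophore_tables(): anchor values at reference wavelengths with the
# characteristic features of the published tabulations (deoxy-hemoglobin 760 nm
# shoulder, ~797 nm isosbestic point, water 970 nm band, collagen 910 nm bump,
# melanin power-law decay), spline-interpolated to a 1 nm grid. They are
# synthetic stand-ins, not the published data; swap in a measured tabulation
# via chromophore_library(path=) for real work.

hemoglobin_anchors <- function() {
  # wavelength, eps_HbO, eps_Hb in 1/(cm*M)
  tibble::tribble(
    ~wl,  ~HbO,  ~Hb,
    650,  368,   3750,
    660,  320,   3227,
    680,  276,   2408,
    700,  290,   1794,
    710,  314,   1540,
    730,  390,   1102,
    750,  518,   1405,
    760,  586,   1549,
    770,  650,   1312,
    780,  710,   1075,
    790,  756,   898,
    800,  816,   762,
    810,  864,   717,
    820,  916,   694,
    840,  1022,  692,
    850,  1058,  691,
    880,  1154,  726,
    900,  1198,  762,
    920,  1232,  796,
    940,  1214,  804,
    960,  1204,  766,
    980,  1184,  686,
    1000, 1150,  628,
    1025, 1078,  560,
    1050, 1002,  504
  )
}

water_anchors <- function() {
  # absorption of pure water, 1/cm
  tibble::tribble(
    ~wl,  ~mua,
    650,  0.0032,
    675,  0.0043,
    700,  0.0060,
    720,  0.0104,
    730,  0.0168,
    740,  0.0257,
    750,  0.0262,
    760,  0.0256,
    770,  0.0235,
    780,  0.0228,
    800,  0.0204,
    820,  0.0258,
    840,  0.0356,
    850,  0.0430,
    860,  0.0471,
    880,  0.0540,
    900,  0.0679,
    910,  0.0762,
    920,  0.1070,
    930,  0.1680,
    940,  0.2670,
    950,  0.3880,
    960,  0.4470,
    970,  0.4850,
    980,  0.4320,
    990,  0.3950,
    1000, 0.3630,
    1015, 0.3050,
    1030, 0.2300,
    1050, 0.1190
  )
}

collagen_anchors <- function() {
  # absorption of 100% (v/v) dry collagen, 1/cm
  tibble::tribble(
    ~wl,  ~mua,
    650,  0.45,
    700,  0.30,
    750,  0.22,
    800,  0.18,
    850,  0.27,
    875,  0.33,
    900,  0.45,
    910,  0.50,
    920,  0.48,
    940,  0.40,
    970,  0.45,
    1000, 0.60,
    1030, 0.90,
    1050, 1.10
  )
}

#' Build the synthetic chromophore table
#'
#' Constructs the 1-nm chromophore library on 650--1050 nm from the anchor
#' tables above. Melanin follows the standard interior-melanosome power law
#' \eqn{1.70\times10^{12}\,\lambda^{-3.48}} 1/cm. The fixed CSF absorption
#' follows the water shape rescaled into its allowed 0.015--0.1 1/cm band and
#' the CSF transport scattering declines linearly from 2.8 to 2.0 1/cm. The
#' grid point nearest the hemoglobin crossing is pinned to the common mean so
#' the table contains an exact isosbestic wavelength.
#'
#' @param wavelengths grid in nm (default 650:1050).
#' @return tibble in [chromophore_library()] column layout.
#' @export
build_chromophore_tables <- function(wavelengths = 650:1050) {
  hb <- hemoglobin_anchors()
  interp <- function(x, y) {
    pmax(stats::spline(x, y, xout = wavelengths, method = "natural")$y, 1e-6)
  }
  eps_HbO <- interp(hb$wl, hb$HbO)
  eps_Hb <- interp(hb$wl, hb$Hb)
  # pin an exact isosbestic point at the grid wavelength nearest the crossing
  i <- which.min(abs(eps_HbO - eps_Hb))
  eps_HbO[i] <- eps_Hb[i] <- (eps_HbO[i] + eps_Hb[i]) / 2

  w <- water_anchors()
  mua_water <- interp(w$wl, w$mua)
  co <- collagen_anchors()
  mua_collagen <- interp(co$wl, co$mua)
  mua_melanin <- 1.70e12 * wavelengths^(-3.48)

  mua_CSF <- 0.015 + 0.085 * (mua_water - min(mua_water)) /
    (max(mua_water) - min(mua_water))
  musp_CSF <- 2.8 + (2.0 - 2.8) * (wavelengths - min(wavelengths)) /
    (max(wavelengths) - min(wavelengths))

  tibble::tibble(
    wavelength_nm = wavelengths,
    eps_HbO = signif(eps_HbO, 6), eps_Hb = signif(eps_Hb, 6),
    mua_water = signif(mua_water, 6), mua_collagen = signif(mua_collagen, 6),
    mua_melanin = signif(mua_melanin, 6), mua_CSF = signif(mua_CSF, 6),
    musp_CSF = signif(musp_CSF, 6)
  )
}

#' Write the chromophore table as a TSV fixture
#'
#' @param path output file.
#' @param lib table from [build_chromophore_tables()].
#' @return `path`, invisibly.
#' @export
write_chromophore_fixture <- function(path,
                                      lib = build_chromophore_tables()) {
  header <- paste(
    "# Synthetic chromophore spectra (1 nm grid, 650-1050 nm).",
    "# eps_* in 1/(cm*M) pairing with tHB in M; mua_* in 1/cm for 100% (v/v)",
    "# volume fraction; mua_CSF/musp_CSF are fixed CSF spectra in 1/cm.",
    sep = "\n")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(lib, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Isosbestic wavelength of a chromophore library
#'
#' @param lib a [chromophore_library()].
#' @return wavelength (nm) where `eps_HbO` and `eps_Hb` are closest.
#' @export
isosbestic_wavelength <- function(lib) {
  lib$wavelength_nm[which.min(abs(lib$eps_HbO - lib$eps_Hb))]
}
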