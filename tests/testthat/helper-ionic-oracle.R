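# Independent transcription of the human ventricular current formulas,
# written in vectorized R directly from the published equation set; used to
# cross-check the compiled implementation. Kept deliberately separate in
# style and structure from the package code.
oracle_currents <- function(st, cell_type = "epi") {
  with(as.list(st), {
    Rg <- 8314.472; Tk <- 310; Fd <- 96485.3415
    rtf <- Rg * Tk / Fd
    Ko <- 5.4; Nao <- 140; Cao <- 2
    EK  <- rtf * log(Ko / k_i)
    ENa <- rtf * log(Nao / na_i)
    EKs <- rtf * log((Ko + 0.03 * Nao) / (k_i + 0.03 * na_i))
    ECa <- 0.5 * rtf * log(Cao / ca_i)

    gto <- if (cell_type == "endo") 0.073 else 0.294
    gks <- if (cell_type == "mid") 0.062 else 0.245

    ak1 <- 0.1 / (1 + exp(0.06 * (v_m - EK - 200)))
    bk1 <- (3 * exp(2e-4 * (v_m - EK + 100)) + exp(0.1 * (v_m - EK - 10))) /
      (1 + exp(-0.5 * (v_m - EK)))
    z <- 2 * v_m / rtf

    out <- c(
      i_na  = 14.838 * m^3 * h * j * (v_m - ENa),
      i_k1  = 5.405 * sqrt(Ko / 5.4) * ak1 / (ak1 + bk1) * (v_m - EK),
      i_to  = gto * r * s * (v_m - EK),
      i_kr  = 0.096 * sqrt(Ko / 5.4) * xr1 * xr2 * (v_m - EK),
      i_ks  = gks * xs^2 * (v_m - EKs),
      i_cal = 0.000175 * d * f * f_ca * 4 * v_m * Fd / rtf *
        (ca_i * exp(z) - 0.341 * Cao) / (exp(z) - 1),
      i_naca = 1000 *
        (exp(0.35 * v_m / rtf) * na_i^3 * Cao -
           exp(-0.65 * v_m / rtf) * Nao^3 * ca_i * 2.5) /
        ((87.5^3 + Nao^3) * (1.38 + Cao) *
           (1 + 0.1 * exp(-0.65 * v_m / rtf))),
      i_nak = 1.362 * Ko * na_i /
        ((Ko + 1) * (na_i + 40) *
           (1 + 0.1245 * exp(-0.1 * v_m / rtf) + 0.0353 * exp(-v_m / rtf))),
      i_pca = 0.825 * ca_i / (5e-4 + ca_i),
      i_pk  = 0.0146 * (v_m - EK) / (1 + exp((25 - v_m) / 5.98)),
      i_bca = 0.000592 * (v_m - ECa),
      i_bna = 0.00029 * (v_m - ENa))
    c(out, i_ion = sum(out))
  })
}
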