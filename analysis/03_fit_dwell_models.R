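#!/usr/bin/env Rscript
# Primary dwell-time fits and secondary Michaelis-Menten analysis.
#
# (i)  Global single-exponential fit (shared binding constant k+, held
#      concentrations) to stall-state dwells simulated at the published
#      Sen1 titration design (3.5/5/10 nM; N = 337/417/564).
# (ii) Global two-step (hypoexponential) maximum-likelihood fit (shared
#      release rate k2, per-condition translocation rate k1) to
#      intermediate lifetimes simulated at the published ATP titration.
# (iii) Weighted classical Michaelis-Menten fits to the published per-ATP
#      rate points, plus the derived translocation and elongation rates.
# Writes results/fits.json and a readable results/fits.tsv.

suppressMessages(library(sen1kin))

seed <- 20260921
out <- list()

## (i) binding-rate titration -------------------------------------------
k_plus_true <- 5.5e6
des <- sen1_titration_design()
hists <- lapply(seq_len(nrow(des)), function(i)
  build_histogram(sample_dwells("single_exp",
                                list(k_plus = k_plus_true, S = des$sen1_M[i]),
                                des$n[i], seed = seed + i)))
f_bind <- fit_global_ls(hists, "single_exp", S = des$sen1_M)
cat(sprintf("Global binding fit: k+ = %.2f x 10^6 M^-1 s^-1 (SE %.2f), reduced chi^2 = %.2f\n",
            f_bind$estimates[["k_plus"]] / 1e6, f_bind$ses[["k_plus"]] / 1e6,
            f_bind$reduced_chisq))
out$binding <- list(k_plus_1e6 = f_bind$estimates[["k_plus"]] / 1e6,
                    se_1e6 = f_bind$ses[["k_plus"]] / 1e6,
                    reduced_chisq = f_bind$reduced_chisq,
                    truth_1e6 = k_plus_true / 1e6)

## (ii) intermediate-lifetime titration ---------------------------------
p1 <- atp_titration_k1()
k2_true <- 8.69
samples <- lapply(seq_len(nrow(p1)), function(i)
  sample_dwells("two_step", list(k1 = p1$k[i], k2 = k2_true), p1$n[i],
                seed = seed + 10 + i))
f_ts <- fit_mle_global(samples, share = "k2")
cat(sprintf("Global two-step MLE: k2 = %.2f s^-1 (SE %.2f); k1 = %s\n",
            f_ts$estimates[["k2"]], f_ts$ses[["k2"]],
            paste(sprintf("%.2f", f_ts$estimates[-1]), collapse = ", ")))
out$two_step <- list(k2 = f_ts$estimates[["k2"]], se = f_ts$ses[["k2"]],
                     k1 = unname(f_ts$estimates[-1]), truth_k2 = k2_true)

## (iii) secondary Michaelis-Menten fits + derived rates ----------------
mm_sets <- list(
  k1_pol2_tether = atp_titration_k1(),
  k1_rna_tether = atp_titration_k1_biornatether(),
  k3_post_termination = atp_titration_k3())
out$mm <- list()
for (nm in names(mm_sets)) {
  p <- mm_sets[[nm]]
  f <- fit_mm_weighted(p$atp_uM, p$k, p$sem)
  cat(sprintf("MM fit %-20s kmax = %.2f +- %.2f s^-1, Km = %.1f +- %.1f uM\n",
              nm, f$estimates[["k_max"]], f$ses[["k_max"]],
              f$estimates[["K_m"]], f$ses[["K_m"]]))
  out$mm[[nm]] <- list(k_max = f$estimates[["k_max"]],
                       k_max_se = f$ses[["k_max"]],
                       K_m = f$estimates[["K_m"]], K_m_se = f$ses[["K_m"]])
}

out$derived <- list(
  translocation_pre_nt_s = translocation_rate(out$mm$k1_pol2_tether$k_max, 14),
  translocation_post_nt_s = translocation_rate(out$mm$k3_post_termination$k_max, 16),
  elongation_bp_s = elongation_rate(28, 2.9),
  elongation_long_bp_s = elongation_rate(539, 47),
  k_cat_s = k_cat_from_mean(0.25))
cat(sprintf("Derived: helicase translocation ~%.0f nt/s (pre) and ~%.0f nt/s (post); polymerase elongation %.1f bp/s\n",
            out$derived$translocation_pre_nt_s,
            out$derived$translocation_post_nt_s,
            out$derived$elongation_bp_s))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(out, "results/fits.json", auto_unbox = TRUE,
                     digits = NA)
tsv <- data.frame(
  quantity = c("k_plus_1e6", "k2_shared",
               paste0("kmax_", names(mm_sets)), paste0("Km_", names(mm_sets)),
               "transloc_pre", "transloc_post", "elong_bp_s"),
  value = c(out$binding$k_plus_1e6, out$two_step$k2,
            sapply(out$mm, `[[`, "k_max"), sapply(out$mm, `[[`, "K_m"),
            out$derived$translocation_pre_nt_s,
            out$derived$translocation_post_nt_s,
            out$derived$elongation_bp_s))
write.table(tsv, "results/fits.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("wrote results/fits.json and results/fits.tsv\n")
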