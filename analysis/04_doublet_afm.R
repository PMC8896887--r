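#!/usr/bin/env Rscript
# Doublet contact-angle mechanics and parallel-plate tension round trips:
# tensions -> angles -> affinity parameter, and synthetic compression
# records decoded back to the imposed tension.
suppressPackageStartupMessages(library(fluctsort))
dir.create("results", showWarnings = FALSE)

# tension triple tuned so the homotypic cosine ratio reproduces 0.79
d_epi <- doublet_from_tensions(1, 1, 1.0)     # EPI::EPI, larger contact
th_epi <- d_epi$theta_e
th_pre <- acos(cos(th_epi * pi / 180) / 0.79) * 180 / pi
g12_pre <- 2 * cos(th_pre * pi / 180)
d_pre <- doublet_from_tensions(1, 1, g12_pre)
beta_hat <- affinity_parameter(d_epi$theta_e, d_pre$theta_e)
message(sprintf("angles: EPI::EPI %.2f deg, PrE::PrE %.2f deg -> beta = %.3f",
                th_epi, d_pre$theta_e, beta_hat))

# measurement round trip through rendered contours, 30 noisy doublets
betas <- vapply(1:30, function(sd) {
  rec <- make_doublet(1, 1, g12_pre, angle_noise_sd = 1.5, seed = sd)
  affinity_parameter(th_epi, rec$theta_2)
}, 0)
message(sprintf("noisy ensemble: beta = %.3f +/- %.3f", mean(betas), sd(betas)))

# AFM inversion
recs <- do.call(rbind, lapply(1:50, function(sd) {
  r <- make_afm_record(T_true = 5e-4, r_mid = 10e-6, h_cell = 9e-6,
                       noise_sd = 0.05, seed = sd)
  data.frame(F = r$F, r_mid = r$r_mid, A_mid = r$A_mid, h_cell = r$h_cell)
}))
batch <- afm_tension_batch(recs, iqr_filter = TRUE)
message(sprintf("AFM: recovered T = %.3e N/m (true 5e-4), kept %d/%d",
                mean(batch$tension[batch$kept]), sum(batch$kept), nrow(batch)))
write.csv(data.frame(beta_point = beta_hat, beta_mean = mean(betas),
                     beta_sd = sd(betas),
                     afm_T = mean(batch$tension[batch$kept])),
          "results/doublet_afm.csv", row.names = FALSE)
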