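# Shared fixtures and independent closed-form oracles.

apt73 <- aptamer_spec("MMC1", full_length_nt = 73L, protected_length_nt = 42L)
noiseless <- digestion_params(noise_cv = 0)
sched240 <- sampling_schedule(seq(0, 240, by = 15))

# exact integral of e^(-k t) over [0, T], valid at k = 0
exp_int <- function(k, T) {
  if (k == 0) T else (1 - exp(-k * T)) / k
}

# closed-form AUC of the slow-exchange digestion model over [0, T]
model_auc_cf <- function(theta, params, omega, T) {
  A <- params$amplitude
  B <- params$background
  ku <- params$k_unprotected
  kl <- params$k_leak
  B * T + A * ((1 - theta) * exp_int(ku, T) +
               theta * (omega * exp_int(kl, T) +
                        (1 - omega) * exp_int(ku + kl, T)))
}

# noiseless resistance value from the closed-form AUCs
model_resistance_cf <- function(theta, params, omega, T) {
  a0 <- model_auc_cf(0, params, omega, T)
  a1 <- model_auc_cf(theta, params, omega, T)
  (a1 - a0) / a0
}

make_control_condition <- function() ligand_condition("none", 0)
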