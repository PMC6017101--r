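# Published single-agent median-effect parameters for the
# bromelain-phytochemical / phospholipase A2 system, used as generating
# truths and for worked examples.
ref_params <- list(
  bromelain      = list(dm = 0.0723, m = 0.6767, r = 0.9879),
  amenthoflavone = list(dm = 0.1079, m = 0.4480, r = 0.9968),
  asiaticoside   = list(dm = 0.3143, m = 0.5258, r = 0.9846),
  diosgenin      = list(dm = 0.9659, m = 0.7018, r = 0.9659)
)

ref_fit <- function(agent) {
  p <- ref_params[[agent]]
  me_fit(dm = p$dm, m = p$m, agent_id = agent)
}

# Published constant-ratio design grid (nominal mg/mL at IC50 multiples
# 2.5, 2, 1, 0.5, 0.2). The diosgenin 2x entry is a known typo in the
# source table (2 x 0.9659 = 1.9318, printed 1.9308) and is excluded from
# exact-reproduction checks.
ref_design <- list(
  multipliers = c(2.5, 2, 1, 0.5, 0.2),
  bromelain      = c(0.1808, 0.1446, 0.0723, 0.03615, 0.01445),
  amenthoflavone = c(0.2698, 0.2158, 0.1079, 0.0540, 0.0216),
  asiaticoside   = c(0.7858, 0.6286, 0.3143, 0.1572, 0.0628),
  diosgenin      = c(2.4148, 1.9308, 0.9659, 0.4829, 0.1932)
)

# exact median-effect dose-effect points
exact_series <- function(dm, m, doses, agent_id = "agent") {
  tibble::tibble(
    agent_id = agent_id,
    dose = doses,
    fraction_affected = 1 / (1 + (dm / doses)^m)
  )
}

# a kinetic trace tibble with readings at the given times
make_trace <- function(sample_id, role, times, od) {
  tibble::tibble(sample_id = sample_id, role = role, time_min = times, od = od)
}

# closed-form additive (Loewe) mixture Dm for two agents sharing slope m
loewe_mix_dm <- function(dm1, dm2, ratio) {
  1 / (ratio / dm1 + (1 - ratio) / dm2)
}
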