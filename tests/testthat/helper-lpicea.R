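# shared fixtures, built in code

# parameter set with every transition probability zeroed: the cohort stays
# in PACS forever, so discounted totals have closed forms
zeroed_transitions <- function(ps = default_parameters()) {
  for (nm in c("p_pacs_pac_lpi", "p_pacs_pac_obs", "p_pac_pacg_lpi",
               "p_pac_pacg_obs", "p_pacg_uniblind", "p_uni_biblind",
               "p_pacs_aacc_obs", "p_pacg_trab_40_49", "p_pacg_trab_50_59"))
    ps <- lpicea:::set_parameter(ps, nm, 0)
  ps
}

# closed-form annuity-due: sum_{t=0}^{n-1} (1+r)^(-t)
annuity_due <- function(n, r) {
  if (r == 0) return(n)
  (1 - (1 + r)^(-n)) / (1 - (1 + r)^(-1))
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

base_icer <- function(ps = default_parameters(),
                      scenario = base_case_scenario()) {
  compare_arms(run_cohort(ps, "lpi", scenario),
               run_cohort(ps, "observation", scenario))$icer
}
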