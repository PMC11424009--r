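# Shared fixtures: small parameter sets and cached synthetic objects.
# Expensive objects (subject, trials, solutions) are built once per test run.

soleus_params <- function(fmax = 6000) {
  muscle_tendon_params(
    name = "soleus", fmax = fmax, l_opt = 0.045, l_slack = 0.28,
    alpha_opt = 0, vmax = 10, slow_twitch_fraction = 0.8, muscle_mass = 0.48,
    joints_spanned = list("ankle")
  )
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

test_subject <- function() cached("subject", make_virtual_subject(1))

test_trial <- function() {
  cached("trial", make_gait_trial(test_subject(), 1.3, seed = 1))
}

test_trial_me <- function() {
  cached("trial_me",
         make_gait_trial(test_subject(), 1.3, seed = 1, truth = "minimal_effort"))
}

test_solution <- function() {
  cached("solution",
         solve_redundancy(test_trial_me(), test_subject()$muscles, "PAS"))
}

test_pipeline <- function() {
  cached("pipeline", run_pipeline(list(
    seed = 4, speeds = 1.3, workflow = "PAS", models = c("BH04", "UM10"),
    subject = test_subject(), trials = list(test_trial_me()),
    n_mesh = 50
  )))
}
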