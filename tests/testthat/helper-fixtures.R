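# Shared fixtures, computed lazily once per session.
.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Normative synthetic trial plus its natural-objective solve and KCF.
normative_case <- function() cache_get("normative", function() {
  model <- default_model()
  gen <- generate_trial(model, trial_config(), seed = 1L)
  solution <- solve_trial(model, gen$trial, objective_spec("natural"))
  kcf <- compute_kcf(model, solution, gen$trial)
  list(model = model, trial = gen$trial, truth = gen$truth,
       solution = solution, kcf = kcf)
})

# Natural vs gastrocnemius-avoidance comparison on the normative trial.
design_case <- function() cache_get("design", function() {
  nc <- normative_case()
  run_design_simulation(nc$model, nc$trial)
})

# EMG-informed solve of the normative trial with synthesized EMG.
emg_informed_case <- function() cache_get("emg_informed", function() {
  nc <- normative_case()
  emg <- generate_emg(nc$truth, seed = 2L)
  ratio <- ratio_spec_from_emg(nc$trial, emg)
  solution <- solve_trial(nc$model, nc$trial, objective_spec("natural"),
                          ratio = ratio)
  list(model = nc$model, trial = nc$trial, truth = nc$truth, emg = emg,
       ratio = ratio, solution = solution)
})

# Single-muscle ankle toy: plantarflexor with zero pennation.
toy_one_muscle <- function(l_s_t = 0.25) {
  planar_model(
    muscles = list(
      pf = list(params = muscle_params("pf", 2000, 0.05, l_s_t, 0),
                arms = list(ankle_plantarflexion = c(0.05)))),
    groups = list(), bodyweight = 736)
}

# Two-muscle ankle toy with identical actuators ("gas_med" so the avoidance
# objective penalizes the first); equal moment arms and force coefficients.
toy_two_muscle <- function() {
  mk <- function(nm) list(params = muscle_params(nm, 2000, 0.05, 0.25, 0),
                          arms = list(ankle_plantarflexion = c(0.05)))
  planar_model(muscles = list(gas_med = mk("gas_med"),
                              soleus = mk("soleus")),
               groups = list(), bodyweight = 736)
}

# Three muscles over two DOFs (knee + ankle) for oracle comparisons.
toy_three_muscle <- function() {
  planar_model(
    muscles = list(
      gas_med = list(params = muscle_params("gas_med", 1600, 0.06, 0.30, 0),
                     arms = list(knee_flexion = c(0.02),
                                 ankle_plantarflexion = c(0.05)),
                     knee_axial = 0.9),
      soleus = list(params = muscle_params("soleus", 3600, 0.05, 0.25, 0),
                    arms = list(ankle_plantarflexion = c(0.05))),
      hams = list(params = muscle_params("hams", 3000, 0.10, 0.30, 0),
                  arms = list(knee_flexion = c(0.034)),
                  knee_axial = 0.75)),
    groups = list(gastrocnemius = "gas_med", hamstrings = "hams"),
    bodyweight = 736)
}

toy_frame <- function(model, M_ID) {
  q <- c(hip_flexion = 0, knee_flexion = 0, ankle_plantarflexion = 0)
  a0 <- setNames(rep(0, length(model$muscles)), names(model$muscles))
  list(q = q, M_ID = M_ID, a_prev = a0)
}

zero_moments <- function() c(hip_flexion = 0, knee_flexion = 0,
                             ankle_plantarflexion = 0)
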