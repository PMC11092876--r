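#' Run configuration for training/ablation experiments
#'
#' One row of the ablation grid: a flow type, a categorical prior family,
#' schedule exponents, model/training/sampling sizes and the seeds to
#' average over. Validation enforces the structural constraints:
#' Dirichlet conditional paths require a uniform-simplex categorical prior
#' (any other combination is rejected), and the `simplexflow` flag marks
#' the combinations whose generated categorical flows are guaranteed to
#' stay on the simplex (simplex-supported prior + endpoint objective).
#'
#' @param flow_type `"endpoint"`, `"vector_field"` or `"dirichlet"`.
#' @param prior_family categorical prior family, see
#'   [categorical_prior_spec()].
#' @param blur_sigma blur width for degenerate simplex priors.
#' @param nu length-4 schedule exponents (X, A, C, E).
#' @param eta length-4 loss weights.
#' @param model list of [flowmol_model()] size arguments.
#' @param train list: `steps`, `batch_size`, `lr`, `ot`.
#' @param sampling list: `count`, `n_steps`.
#' @param seeds integer vector; the run is repeated per seed and averaged.
#' @param omega_max Dirichlet concentration cap.
#' @param name optional label.
#' @return validated object of class `run_config`.
#' @export
run_config <- function(flow_type = c("endpoint", "vector_field", "dirichlet"),
                       prior_family = "gaussian", blur_sigma = 0.15,
                       nu = c(1, 1, 1, 1), eta = c(3, 0.4, 1, 2),
                       model = list(), train = list(), sampling = list(),
                       seeds = c(1L, 2L), omega_max = 100, name = NULL) {
  flow_type <- match.arg(flow_type)
  prior_family <- match.arg(prior_family,
                            c("gaussian", "uniform-simplex",
                              "marginal-simplex", "barycenter"))
  if (flow_type == "dirichlet" && prior_family != "uniform-simplex") {
    stop("Dirichlet conditional paths require the uniform-simplex prior; got ",
         prior_family)
  }
  model <- utils::modifyList(list(n_blocks = 2, scalar_dim = 32,
                                  vector_dim = 4, edge_dim = 16, rbf_dim = 8,
                                  cross_products = TRUE), model)
  train <- utils::modifyList(list(steps = 200, batch_size = 8, lr = 2e-3,
                                  ot = TRUE), train)
  sampling <- utils::modifyList(list(count = 50, n_steps = 50), sampling)
  simplexflow <- flow_type %in% c("endpoint", "dirichlet") &&
    prior_family %in% c("uniform-simplex", "marginal-simplex", "barycenter")
  if (is.null(name)) name <- paste(flow_type, prior_family, sep = " | ")
  structure(list(flow_type = flow_type, prior_family = prior_family,
                 blur_sigma = blur_sigma, nu = nu, eta = eta, model = model,
                 train = train, sampling = sampling,
                 seeds = as.integer(seeds), omega_max = omega_max,
                 simplexflow = simplexflow, name = name),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a validated [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, obj)
}

run_one <- function(cfg, mols, seed) {
  set.seed(seed)
  cb <- mols[[1]]$codebook
  schedules <- schedule_set(cfg$nu[1], cfg$nu[2], cfg$nu[3], cfg$nu[4])
  prior <- estimate_molecule_prior(mols, family = cfg$prior_family,
                                   blur_sigma = cfg$blur_sigma)
  objective <- if (cfg$flow_type == "vector_field") "vector_field" else
    "endpoint"
  model <- do.call(flowmol_model,
                   c(list(codebook = cb, objective = objective,
                          schedules = schedules), cfg$model))
  fit <- train_flowmol(model, mols, prior, steps = cfg$train$steps,
                       batch_size = cfg$train$batch_size, lr = cfg$train$lr,
                       ot = cfg$train$ot, eta = cfg$eta,
                       flow_type = if (cfg$flow_type == "dirichlet")
                         "dirichlet" else "linear",
                       omega_max = cfg$omega_max)
  sampled <- sample_molecules(fit$model, prior, cfg$sampling$count,
                              sampling_config(n_steps = cfg$sampling$n_steps))
  list(model = fit$model, loss = fit$loss, sampled = sampled, prior = prior)
}

#' Run an ablation grid on a fixture molecule set
#'
#' Trains every configuration at its stated (desk) scale, samples and
#' evaluates it, repeating per seed, and returns one summary row per config
#' with seed-averaged metrics — the shape of the usual
#' "flow type | categorical prior | stability | validity | JS(E)" ablation
#' table.
#'
#' @param configs list of [run_config()].
#' @param mols training/reference molecules (one-hot, centered).
#' @param with_energy also compute the JS energy divergence (needs RDKit).
#' @return data.frame, one row per config.
#' @export
run_ablation_grid <- function(configs, mols, with_energy = FALSE) {
  table <- build_valency_table(mols)
  rows <- lapply(configs, function(cfg) {
    per_seed <- lapply(cfg$seeds, function(seed) {
      run <- run_one(cfg, mols, seed)
      st <- stability(run$sampled, table)
      va <- tryCatch(validity(run$sampled),
                     error = function(e) list(mols_valid_pct = NA_real_))
      js <- if (with_energy) {
        tryCatch(js_energy_divergence(run$sampled, mols)$js,
                 error = function(e) NA_real_)
      } else NA_real_
      c(atoms_stable_pct = st$atoms_stable_pct,
        mols_stable_pct = st$mols_stable_pct,
        mols_valid_pct = va$mols_valid_pct,
        js_energy = js, final_loss = mean(utils::tail(run$loss, 20)))
    })
    m <- colMeans(do.call(rbind, per_seed))
    data.frame(name = cfg$name, flow_type = cfg$flow_type,
               prior = cfg$prior_family, n_seeds = length(cfg$seeds),
               atoms_stable_pct = m[["atoms_stable_pct"]],
               mols_stable_pct = m[["mols_stable_pct"]],
               mols_valid_pct = m[["mols_valid_pct"]],
               js_energy = m[["js_energy"]],
               final_loss = m[["final_loss"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
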