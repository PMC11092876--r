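# Text (JSON) checkpoint serialization. Checkpoints carry everything needed
# to resume or sample: codebook, schedule exponents, model config and
# parameters, and the molecule prior (families, marginals, atom-count
# histogram). Matrices are stored column-major with their dimensions.

mat_to_list <- function(m) list(.mat = TRUE, dim = dim(m), data = as.numeric(m))

list_to_mat <- function(x) matrix(unlist(x$data), unlist(x$dim)[1],
                                  unlist(x$dim)[2])

params_to_list <- function(p) {
  if (is.matrix(p)) return(mat_to_list(p))
  lapply(p, params_to_list)
}

params_from_list <- function(x) {
  if (!is.null(x$.mat)) return(list_to_mat(x))
  lapply(x, params_from_list)
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

prior_to_list <- function(prior) {
  spec1 <- function(s) drop_null(list(family = s$family,
                                      blur_sigma = s$blur_sigma, q = s$q))
  drop_null(list(
    a = spec1(prior$a), c = spec1(prior$c), e = spec1(prior$e),
    atom_count_hist = list(counts = names(prior$atom_count_hist),
                           probs = as.numeric(prior$atom_count_hist)),
    ac_joint = if (is.null(prior$ac_joint)) NULL else
      mat_to_list(prior$ac_joint)))
}

prior_from_list <- function(x) {
  spec1 <- function(s) {
    q <- unlist(s$q)  # NULL when absent or empty
    categorical_prior_spec(s$family, blur_sigma = s$blur_sigma, q = q)
  }
  hist <- unlist(x$atom_count_hist$probs)
  names(hist) <- unlist(x$atom_count_hist$counts)
  has_joint <- !is.null(x$ac_joint) && !is.null(x$ac_joint$.mat)
  molecule_prior_spec(spec1(x$a), spec1(x$c), spec1(x$e), hist,
                      ac_joint = if (has_joint) list_to_mat(x$ac_joint) else
                        NULL)
}

#' Save a model checkpoint (JSON)
#'
#' @param model a [flowmol_model()].
#' @param path output path.
#' @param prior optional [molecule_prior_spec()] stored alongside the model
#'   so sampling needs nothing else.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, prior = NULL) {
  obj <- list(package = "molfm", format = 1L,
              codebook = codebook_to_list(model$codebook),
              schedules = schedule_set_to_list(model$schedules),
              config = model$config,
              params = params_to_list(model$params),
              prior = if (is.null(prior)) NULL else prior_to_list(prior))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint path written by [save_checkpoint()].
#' @return list: `model` (a [flowmol_model()]) and `prior` (a
#'   [molecule_prior_spec()] or NULL).
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$package, "molfm")) stop("not a molfm checkpoint")
  cb <- codebook_from_list(obj$codebook)
  cfg <- obj$config
  model <- flowmol_model(cb, n_blocks = cfg$n_blocks,
                         scalar_dim = cfg$scalar_dim,
                         vector_dim = cfg$vector_dim, edge_dim = cfg$edge_dim,
                         rbf_dim = cfg$rbf_dim, rbf_max = cfg$rbf_max,
                         cross_products = cfg$cross_products,
                         objective = cfg$objective,
                         schedules = schedule_set_from_list(obj$schedules))
  model$params <- params_from_list(obj$params)
  list(model = model,
       prior = if (is.null(obj$prior)) NULL else prior_from_list(obj$prior))
}
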