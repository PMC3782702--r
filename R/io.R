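# Configuration files and exporters.

#' Read a generative model from a YAML configuration file
#'
#' The schema mirrors [generative_model()]:
#' \preformatted{
#' horizon: 3
#' alpha: 8
#' beta: 1
#' A: [[1, 0], [0, 1]]          # rows of the observation matrix
#' B:
#'   - [[0.9, 0], [0.1, 1]]     # control 1: a single J x J matrix (rows), or
#'   - per_time:                # a list of matrices, one per trial
#'       - [[1, 0], [0, 1]]
#'       - [[1, 0], [0, 1]]
#'       - [[1, 0], [0, 1]]
#' utilities: [0, 2]            # or `c:` for an explicit goal prior
#' d: [1, 0]
#' }
#' A top-level `game: limited_offer` entry instead builds the built-in game,
#' with optional keys `horizon`, `utilities`, `withdrawal_base`,
#' `high_offer_total`, `alpha`, `beta`, `preclude_withdrawal`,
#' `preclude_action` passed to [limited_offer_params()].
#'
#' @param path Path to the YAML file.
#' @return A [generative_model()], or for `game: limited_offer` the list
#'   returned by [build_limited_offer()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (identical(cfg$game, "limited_offer")) {
    keys <- intersect(names(cfg),
                      names(formals(limited_offer_params)))
    return(build_limited_offer(do.call(limited_offer_params, cfg[keys])))
  }
  as_mat <- function(x) do.call(rbind, lapply(x, as.numeric))
  B <- lapply(cfg$B, function(b) {
    if (!is.null(b$per_time)) lapply(b$per_time, as_mat) else as_mat(b)
  })
  generative_model(A = as_mat(cfg$A), B = B,
                   c = cfg$c, utilities = cfg$utilities,
                   d = as.numeric(cfg$d), horizon = cfg$horizon,
                   alpha = cfg$alpha %||% 8, beta = cfg$beta %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a game trace to CSV (one row per trial)
#'
#' @param trace A [run_game()] trace.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_game_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write a full nested game trace to JSON (including per-sweep iterations)
#'
#' @param trace A [run_game()] trace.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_game_trace_json <- function(trace, path) {
  payload <- list(
    summary = as.data.frame(trace),
    gamma_sweeps = data.frame(trial = trace$sweep_trial,
                              gamma_hat = trace$gamma_sweeps),
    states = trace$states, actions = trace$actions)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a value matrix and its decomposition to CSV
#'
#' @param value A [compute_value_matrix()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_value_matrix_csv <- function(value, path) {
  utils::write.csv(as.data.frame(value), path, row.names = FALSE)
  invisible(path)
}

#' Write the per-sweep iteration trace of a game to CSV
#'
#' @param trace A [run_game()] trace.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_iteration_trace_csv <- function(trace, path) {
  rows <- do.call(rbind, lapply(trace$trials, function(x)
    cbind(trial = x$trial, x$trace)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
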