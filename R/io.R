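#' Read a behavioural trial table
#'
#' Reads a delimited text file with one row per trial and the header
#' columns `trial`, `state`, `action`, `reward`, `next_state`, `rt`
#' (`rt` optional, `NA` allowed). Columns are type-checked and rows are
#' returned sorted by trial; malformed rows raise an error naming the row.
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @return A tibble with typed columns, sorted by `trial`.
#' @export
load_trials <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(empty_trials())
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(df) == 0L && ncol(df) == 0L) return(empty_trials())
  required <- c("trial", "state", "action", "reward", "next_state")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!("rt" %in% names(df))) df$rt <- NA_real_
  for (col in c("trial", "reward", "rt")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at row %d", col,
                   bad[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  bad_rt <- which(!is.na(df$rt) & df$rt < 0)
  if (length(bad_rt)) {
    stop(sprintf("negative rt at row %d", bad_rt[1]), call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$trial)
  tibble::as_tibble(df[c(required, "rt")])
}

empty_trials <- function() {
  tibble::tibble(trial = numeric(), state = character(),
                 action = character(), reward = numeric(),
                 next_state = character(), rt = numeric())
}

#' Write a behavioural trial table
#'
#' @param trials A tibble with the trial-table columns.
#' @param path Output path (tab-delimited text with header).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_tsv(trials, path, progress = FALSE)
  invisible(path)
}

#' Convert a simulated bandit session to the trial-table format
#'
#' @param session A `hafvf_session` (see [run_session()]).
#' @return A tibble in the `load_trials()` column layout (single state
#'   task: `state` and `next_state` are `"s1"`).
#' @export
session_to_trials <- function(session) {
  tibble::tibble(trial = session$trial, state = "s1",
                 action = paste0("a", session$choice),
                 reward = session$reward, next_state = "s1",
                 rt = session$rt)
}

## ---------------------------------------------------------------------------

#' Default run configuration
#'
#' Flat, YAML-compatible configuration covering the agent priors, the
#' diffusion parameters and the run options. Unknown keys are rejected on
#' load; every domain constraint is validated.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    mu0 = 0, kappa0 = 0.1, alpha0 = 1, beta0 = 1,
    phi_a = 4.5, phi_b = 0.5, bet_a = 4.5, bet_b = 0.5,
    gamma_a = NA, gamma_b = NA, pi0 = 5,
    zeta = 2, z0_rel = 0.5, tau = 0.3,
    counterfactual = "continuous", td = FALSE,
    dt = 1e-3, tol = 1e-3, max_iter = 50, damping = 0.8,
    n_mc = 8, seed = 1
  )
}

#' Load and validate a run configuration
#'
#' @param path Path to a YAML (or flat `key: value`) configuration file;
#'   `NULL` returns the defaults.
#' @return A validated configuration list with elements `priors`
#'   ([agent_priors()]), `ddm` ([ddm_params()]) and `options`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  gamma0 <- if (!is.na(cfg$gamma_a) && !is.na(cfg$gamma_b)) {
    beta_belief(cfg$gamma_a, cfg$gamma_b)
  } else if (isTRUE(cfg$td)) {
    beta_belief(9, 1)
  } else {
    NULL
  }
  priors <- agent_priors(
    theta0 = nig_posterior(cfg$mu0, cfg$kappa0, cfg$alpha0, cfg$beta0),
    phi0 = beta_belief(cfg$phi_a, cfg$phi_b),
    beta0 = beta_belief(cfg$bet_a, cfg$bet_b),
    gamma0 = gamma0, pi0 = cfg$pi0)
  stopifnot(cfg$dt > 0, cfg$tol > 0, cfg$max_iter >= 1,
            cfg$damping > 0, cfg$damping <= 1, cfg$n_mc >= 1,
            cfg$counterfactual %in% c("continuous", "none"),
            cfg$z0_rel > 0, cfg$z0_rel < 1)
  list(priors = priors,
       ddm = ddm_params(cfg$zeta, cfg$zeta * cfg$z0_rel, cfg$tau),
       options = cfg)
}

#' Write the full configuration (defaults merged with overrides) to YAML
#'
#' @param path Output path.
#' @param config Configuration list (flat form, as in [default_config()]).
#' @return `path`, invisibly.
#' @export
dump_config <- function(path, config = default_config()) {
  yaml::write_yaml(config, path)
  invisible(path)
}
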