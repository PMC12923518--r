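#' MAP fit of a learning model to one subject
#'
#' Maximises log-likelihood plus log-prior over the free parameters on
#' their unconstrained scale with quasi-Newton (BFGS) local optimisation
#' from `n_restarts` starts: the prior mean first, then starts jittered by
#' one prior SD. The best converged optimum is returned with a numerical
#' Hessian of the negative log joint at the mode and the Laplace
#' approximation to the log model evidence (see [log_evidence()]).
#'
#' @param dataset subject trial data frame (see [log_likelihood()]),
#'   at least 2 trials.
#' @param model_spec model label, one of [costlearn_models()].
#' @param priors prior specification as returned by [default_priors()]
#'   (override rows to change means/SDs or fix parameters).
#' @param n_restarts number of optimisation starts (default 10).
#' @param seed optional integer seed for the start jitter.
#' @return an object of class `costlearn_fit`: `model`, `theta`
#'   (unconstrained MAP, free parameters), `estimates` (native-scale, all
#'   parameters), `log_joint`, `log_lik`, `hessian`, `log_evidence`,
#'   `converged`, `n_restarts`, `best_objective`, `evidence_method`,
#'   `n_trials`, `priors`.
#' @examples
#' \dontrun{
#' sched <- generate_schedule("stable_first", seed = 1)
#' dat <- simulate_agent("hgf2", list(omega = -2, beta = 2), sched, seed = 2)
#' fit <- fit_map(dat, "hgf2", seed = 3)
#' fit$estimates
#' }
#' @export
fit_map <- function(dataset, model_spec,
                    priors = default_priors(model_spec),
                    n_restarts = 10, seed = NULL) {
  model_spec <- match.arg(model_spec, costlearn_models())
  priors <- check_priors(priors, model_spec)
  if (nrow(dataset) < 2) stop("dataset needs at least 2 trials")
  if (!is.null(seed)) set.seed(seed)

  u <- reference_outcome(dataset)
  mag1 <- dataset$mag_card1
  mag2 <- dataset$mag_card2
  choice <- dataset$choice

  free <- !priors$fixed
  free_tab <- priors[free, , drop = FALSE]
  fixed_tab <- priors[!free, , drop = FALSE]
  d <- nrow(free_tab)

  assemble <- function(theta) {
    params <- theta_to_params(theta, free_tab)
    if (nrow(fixed_tab))
      for (j in seq_len(nrow(fixed_tab)))
        params[[fixed_tab$name[j]]] <- fixed_tab$fixed_native[j]
    params
  }
  neg_log_joint <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    ll <- ll_fast(model_spec, assemble(theta), u, mag1, mag2, choice)
    lp <- sum(stats::dnorm(theta, free_tab$mean, free_tab$sd, log = TRUE))
    v <- -(ll + lp)
    if (!is.finite(v)) 1e10 else v
  }

  starts <- matrix(rep(free_tab$mean, n_restarts), ncol = d, byrow = TRUE)
  if (n_restarts > 1) {
    # row-wise fill so the first k jittered starts coincide for any
    # n_restarts >= k under the same seed (restart sets are nested)
    jit <- matrix(stats::rnorm((n_restarts - 1) * d), ncol = d, byrow = TRUE)
    starts[-1, ] <- starts[-1, , drop = FALSE] +
      jit * rep(free_tab$sd, each = n_restarts - 1)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    opt <- tryCatch(
      stats::optim(starts[r, ], neg_log_joint, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-6)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("no converged restart for subject '",
         dataset$subject_id[1], "', model '", model_spec, "'")

  theta <- best$par
  names(theta) <- free_tab$name
  H <- tryCatch(stats::optimHess(theta, neg_log_joint),
                error = function(e) matrix(NA_real_, d, d))
  dimnames(H) <- list(free_tab$name, free_tab$name)
  params <- assemble(theta)

  fit <- structure(list(model = model_spec,
                        theta = theta,
                        estimates = params,
                        log_joint = -best$value,
                        log_lik = ll_fast(model_spec, params, u, mag1, mag2,
                                          choice),
                        hessian = H,
                        converged = best$convergence == 0,
                        n_restarts = n_restarts,
                        best_objective = best$value,
                        n_trials = nrow(dataset),
                        subject_id = dataset$subject_id[1],
                        priors = priors),
                   class = "costlearn_fit")
  ev <- log_evidence(fit)
  fit$log_evidence <- ev
  fit$evidence_method <- attr(ev, "method")
  fit
}

#' @export
print.costlearn_fit <- function(x, ...) {
  cat("costlearn fit:", x$model, "| subject", x$subject_id, "\n")
  cat("  estimates:", paste(names(x$estimates),
                            signif(unlist(x$estimates), 4),
                            sep = "=", collapse = ", "), "\n")
  cat("  log evidence:", round(x$log_evidence, 3),
      "(", x$evidence_method, ")\n")
  invisible(x)
}

#' Laplace-approximated log model evidence
#'
#' Approximates the log marginal likelihood of a subject's choices under a
#' fitted model as
#' `log_joint(MAP) + (d/2) log(2*pi) - 0.5 log det(H)`, where `H` is the
#' Hessian of the negative log joint density at the MAP and `d` the number
#' of free parameters. If `H` is not positive definite it is ridge
#' regularised; if that fails, a BIC-style approximation
#' `log_lik(MAP) - (d/2) log(n_trials)` is returned instead, flagged via
#' the `"method"` attribute (`"laplace"`, `"laplace_ridge"` or `"bic"`).
#'
#' @param fit a `costlearn_fit`.
#' @return scalar log evidence with a `"method"` attribute.
#' @export
log_evidence <- function(fit) {
  H <- fit$hessian
  d <- nrow(H)
  method <- "laplace"
  logdet <- NA_real_
  if (all(is.finite(H))) {
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) {
      ridge <- mean(abs(diag(H))) * 1e-6 + 1e-8
      for (k in 1:8) {
        ch <- tryCatch(chol(H + diag(ridge, d)), error = function(e) NULL)
        if (!is.null(ch)) { method <- "laplace_ridge"; break }
        ridge <- ridge * 10
      }
    }
    if (!is.null(ch)) logdet <- 2 * sum(log(diag(ch)))
  } else {
    ch <- NULL
  }
  if (is.na(logdet)) {
    ev <- fit$log_lik - (d / 2) * log(fit$n_trials)
    method <- "bic"
  } else {
    ev <- fit$log_joint + (d / 2) * log(2 * pi) - 0.5 * logdet
  }
  attr(ev, "method") <- method
  ev
}

#' Fit several models to every subject of a cohort
#'
#' @param trials trial-level data frame for one or more subjects (or a
#'   `costlearn_cohort`).
#' @param models character vector of model labels.
#' @param n_restarts,seed passed to [fit_map()] (per-subject seeds are
#'   derived from `seed`).
#' @param priors optional named list of prior specifications per model.
#' @param progress print a line per subject.
#' @return a list with `table` (data frame: `subject_id`, `model`,
#'   native-scale parameter columns, `log_evidence`, `converged`) and
#'   `fits` (nested list `fits[[subject]][[model]]`). Subjects whose fit
#'   fails for a model get `NA` rows and are flagged.
#' @export
fit_cohort <- function(trials, models = costlearn_models(), n_restarts = 10,
                       seed = 1L, priors = NULL, progress = FALSE) {
  if (inherits(trials, "costlearn_cohort")) trials <- trials$trials
  if (!length(models)) stop("empty model list")
  models <- vapply(models, match.arg, "", choices = costlearn_models())
  subjects <- split(trials, trials$subject_id)
  rows <- list()
  fits <- list()
  i <- 0L
  for (sid in names(subjects)) {
    i <- i + 1L
    if (progress) message("fitting subject ", sid, " (", i, "/",
                          length(subjects), ")")
    fits[[sid]] <- list()
    for (m in models) {
      pr <- if (!is.null(priors) && !is.null(priors[[m]])) priors[[m]]
            else default_priors(m)
      f <- tryCatch(
        fit_map(subjects[[sid]], m, priors = pr, n_restarts = n_restarts,
                seed = seed + 7L * i + match(m, models)),
        error = function(e) e)
      fits[[sid]][[m]] <- f
      if (inherits(f, "error")) {
        warning("fit failed for subject ", sid, ", model ", m, ": ",
                conditionMessage(f))
        rows[[length(rows) + 1L]] <-
          data.frame(subject_id = sid, model = m, log_evidence = NA_real_,
                     converged = FALSE, stringsAsFactors = FALSE)
      } else {
        row <- data.frame(subject_id = sid, model = m,
                          log_evidence = as.numeric(f$log_evidence),
                          converged = f$converged, stringsAsFactors = FALSE)
        for (p in names(f$estimates)) row[[p]] <- f$estimates[[p]]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  list(table = do.call(rbind, rows), fits = fits)
}

#' Subjects-by-models log-evidence matrix
#'
#' @param fits_table the `table` element of [fit_cohort()] output.
#' @return numeric matrix (subjects x models) of log evidences.
#' @export
evidence_matrix <- function(fits_table) {
  subjects <- unique(fits_table$subject_id)
  models <- unique(fits_table$model)
  m <- matrix(NA_real_, length(subjects), length(models),
              dimnames = list(subjects, models))
  for (i in seq_len(nrow(fits_table)))
    m[fits_table$subject_id[i], fits_table$model[i]] <-
      fits_table$log_evidence[i]
  m
}
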