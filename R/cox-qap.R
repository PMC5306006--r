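#' Fit an extended Cox proportional-hazards model to interval records
#'
#' Fits the hazard model `h(t, X) = h0(t) exp(sum_i beta_i X_i)` on
#' counting-process records, so covariates may vary over a subject's life
#' (the extended Cox model). Colony always enters the model — as a
#' categorical fixed effect by default, or as a stratum — because nests of
#' one colony share unmeasured conditions. Ties are handled by the Efron
#' approximation by default (event times have interval granularity, so
#' ties are heavy); Breslow is available. Rows with a missing covariate
#' are dropped (complete-case) and the n actually used is reported.
#'
#' @param records Tibble from [build_survival_records()] (or any table
#'   with `subject_id`, `colony_id`, `start`, `stop`, `event` and the
#'   covariate columns).
#' @param covariates Character vector of covariate column names (X_1 ...
#'   X_p).
#' @param colony `"factor"` (default) or `"stratum"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An `nf_cox` object: list with the underlying
#'   [survival::coxph()] `fit`, a `coefficients` tibble (`term`, `beta`,
#'   `se`, `z`), `loglik` (null and fitted), `baseline` cumulative-hazard
#'   tibble, `n_rows`, `n_subjects`, `n_events` and the resolved spec.
#' @examples
#' recs <- tibble::tibble(
#'   subject_id = letters[1:8], colony_id = "c1",
#'   start = 0, stop = c(1, 1, 2, 2, 3, 3, 3, 3),
#'   event = c(1, 1, 1, 0, 1, 0, 0, 0),
#'   betweenness = c(.1, .2, .4, .9, .3, .8, .9, 1))
#' fit <- fit_extended_cox(recs, "betweenness", colony = "stratum")
#' tidy(fit)
#' @export
fit_extended_cox <- function(records, covariates,
                             colony = c("factor", "stratum"),
                             ties = c("efron", "breslow")) {
  colony <- match.arg(colony)
  ties <- match.arg(ties)
  if (length(covariates) == 0L) abort("at least one covariate is required")
  missing_cols <- setdiff(c(covariates, "start", "stop", "event",
                            "colony_id", "subject_id"), names(records))
  if (length(missing_cols)) {
    abort(paste("records are missing column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  dat <- records[stats::complete.cases(records[, covariates, drop = FALSE]), ,
                 drop = FALSE]
  if (nrow(dat) < nrow(records)) {
    inform(paste0("dropped ", nrow(records) - nrow(dat),
                  " record(s) with missing covariates; n = ", nrow(dat)))
  }
  if (sum(dat$event) < 1L) abort("no events in the records: nothing to fit")
  for (cv in covariates) {
    if (length(unique(dat[[cv]])) < 2L) {
      abort(paste0("covariate is constant across records: ", cv,
                   " (singular information)"))
    }
  }
  multi_colony <- length(unique(dat$colony_id)) > 1L
  colony_term <- if (!multi_colony) {
    NULL
  } else if (colony == "factor") {
    "factor(colony_id)"
  } else {
    "survival::strata(colony_id)"
  }
  rhs <- paste(c(covariates, colony_term), collapse = " + ")
  fml <- stats::as.formula(paste(
    "survival::Surv(start, stop, event) ~", rhs))
  fit <- survival::coxph(fml, data = dat, ties = ties, model = TRUE,
                         x = TRUE, y = TRUE)
  cf <- coef(fit)
  if (any(is.na(cf))) {
    abort(paste0("singular information: inestimable term(s) ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  if (any(abs(cf[covariates]) > 15)) {
    warn(paste0("partial likelihood is monotone (separation) in: ",
                paste(covariates[abs(cf[covariates]) > 15],
                      collapse = ", "),
                "; that coefficient is not interpretable"))
  }
  se_vec <- sqrt(diag(as.matrix(vcov(fit))))
  names(se_vec) <- names(cf)
  base <- tryCatch(
    as_tibble(survival::basehaz(fit, centered = FALSE))[,
      c("time", "hazard")],
    error = function(e) tibble(time = numeric(), hazard = numeric()))
  structure(list(
    fit = fit,
    data = dat,
    coefficients = tibble(term = names(cf), beta = unname(cf),
                          se = unname(se_vec),
                          z = unname(cf / se_vec)),
    loglik = c(null = fit$loglik[1], fitted = fit$loglik[2]),
    baseline = base,
    n_rows = nrow(dat),
    n_subjects = length(unique(dat$subject_id)),
    n_events = sum(dat$event),
    spec = list(covariates = covariates, colony = colony, ties = ties)
  ), class = "nf_cox")
}

#' @export
print.nf_cox <- function(x, ...) {
  cat(sprintf("<nf_cox> %d records, %d subjects, %d events; ties = %s\n",
              x$n_rows, x$n_subjects, x$n_events, x$spec$ties))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  invisible(x)
}

#' @method tidy nf_cox
#' @export
tidy.nf_cox <- function(x, ...) {
  x$coefficients |>
    rename(estimate = "beta", std.error = "se", statistic = "z")
}

#' @method glance nf_cox
#' @export
glance.nf_cox <- function(x, ...) {
  tibble(n = x$n_rows, n_subjects = x$n_subjects, n_events = x$n_events,
         logLik_null = unname(x$loglik["null"]),
         logLik = unname(x$loglik["fitted"]))
}

#' Shuffle a node attribute within each colony map
#'
#' The quadratic assignment procedure builds its null by permuting the
#' tested node attribute among the subjects of each map — each
#' colony-by-timepoint map is an exchangeable block, and values never
#' cross colony or timepoint boundaries. Only the named covariate moves;
#' every other column (including co-adjusted covariates) keeps its
#' observed association structure.
#'
#' @param records Counting-process records with `colony_id` and
#'   `timepoint` identifying the map each row's covariate was measured in.
#' @param covariate Column to shuffle.
#' @param warn_singletons Inform about maps with a single subject (whose
#'   value cannot move)? Default `FALSE`.
#' @return `records` with the covariate permuted within maps.
#' @export
permute_within_maps <- function(records, covariate,
                                warn_singletons = FALSE) {
  if (!covariate %in% names(records)) {
    abort(paste0("covariate not found in records: ", covariate))
  }
  key <- paste(records$colony_id, records$timepoint, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  if (warn_singletons) {
    n1 <- sum(vapply(groups, length, 1L) == 1L)
    if (n1 > 0) {
      inform(paste0(n1, " map(s) hold a single subject; their value is fixed"))
    }
  }
  x <- records[[covariate]]
  for (idx in groups) {
    if (length(idx) > 1L) {
      x[idx] <- x[idx][sample.int(length(idx))]
    }
  }
  records[[covariate]] <- x
  records
}

#' QAP permutation test for a covariate in the extended Cox model
#'
#' Survival records derived from a network violate the independence
#' assumed by the Cox partial likelihood, so significance is taken not
#' from the asymptotic Wald test but from a quadratic-assignment null: the
#' covariate of interest is shuffled within each colony map, the model is
#' refitted, and the observed z statistic is ranked within the resulting
#' null distribution. The p-value uses the add-one estimator
#' `(1 + #extreme) / (1 + B)`, which is valid under exchangeability and
#' never smaller than `1/(B+1)`. Permutation refits that fail are dropped
#' from the null and counted; the result is flagged unreliable when more
#' than 5% fail.
#'
#' @inheritParams fit_extended_cox
#' @param covariate Covariate whose effect is tested (default: the first
#'   of `covariates`).
#' @param B Number of permutations (default 10000).
#' @param tail `"two_sided"` (default), `"lower"` or `"upper"`.
#' @param seed Integer seed; the whole test is reproducible from it.
#' @return A `qap_cox` object: observed fit and z, `null_stats`, `B`
#'   requested and achieved, `p_value`, `tail`, `seed`, `n`,
#'   `n_failed` and `unreliable` flag.
#' @examples
#' \donttest{
#' sim <- simulate_colonies(sim_config(n_colonies = 4, seed = 7))
#' recs <- build_survival_records(sim$colonies)
#' qap_cox(recs, "betweenness", B = 99, seed = 1)
#' }
#' @export
qap_cox <- function(records, covariates, covariate = covariates[1],
                    colony = c("factor", "stratum"),
                    ties = c("efron", "breslow"),
                    B = 10000, tail = c("two_sided", "lower", "upper"),
                    seed = 1L) {
  tail <- match.arg(tail)
  colony <- match.arg(colony)
  ties <- match.arg(ties)
  if (B < 100) warn("B < 100 permutations gives a very coarse p-value")
  if (!covariate %in% covariates) {
    abort("`covariate` must be one of `covariates`")
  }
  observed <- fit_extended_cox(records, covariates, colony, ties)
  beta_obs <- observed$coefficients$beta[observed$coefficients$term ==
                                           covariate]
  if (abs(beta_obs) > 15) {
    abort(paste0("the tested covariate is separable (monotone partial ",
                 "likelihood): ", covariate))
  }
  z_obs <- observed$coefficients$z[observed$coefficients$term == covariate]

  set.seed(as.integer(seed))
  # deterministic per-permutation substreams: results do not depend on
  # execution order
  sub_seeds <- sample.int(.Machine$integer.max - 1L, B)
  null_stats <- rep(NA_real_, B)

  # refits reuse the observed design matrix, with only the tested column
  # permuted, so each permutation needs one partial-likelihood
  # maximisation and no model-frame rebuild (identical estimates to a
  # full refit; the stratified model keeps the full path)
  dat <- observed$data
  fast <- colony == "factor" &&
    covariate %in% colnames(observed$fit$x) &&
    isTRUE(all.equal(unname(observed$fit$x[, covariate]),
                     dat[[covariate]]))
  if (fast) {
    X <- observed$fit$x
    Y <- observed$fit$y
    col_j <- match(covariate, colnames(X))
    ctrl <- survival::coxph.control()
    # the map blocks never change, so compute them once; per-permutation
    # draws then match permute_within_maps() call for call
    key <- paste(dat$colony_id, dat$timepoint, sep = "\r")
    groups <- split(seq_len(nrow(dat)), key)
    groups <- groups[lengths(groups) > 1L]
    x0 <- dat[[covariate]]
    for (b in seq_len(B)) {
      set.seed(sub_seeds[b])
      xp <- x0
      for (idx in groups) xp[idx] <- xp[idx][sample.int(length(idx))]
      Xp <- X
      Xp[, col_j] <- xp
      f <- tryCatch(
        suppressWarnings(survival::agreg.fit(
          Xp, Y, strata = NULL, offset = NULL, init = NULL,
          control = ctrl, weights = NULL, method = ties,
          rownames = NULL)),
        error = function(e) NULL)
      if (!is.null(f) && !is.na(f$coefficients[col_j]) &&
          abs(f$coefficients[col_j]) <= 15) {
        null_stats[b] <-
          f$coefficients[col_j] / sqrt(diag(f$var))[col_j]
      }
    }
  } else {
    for (b in seq_len(B)) {
      set.seed(sub_seeds[b])
      perm <- records
      perm[[covariate]] <-
        permute_within_maps(records[, c("colony_id", "timepoint",
                                        covariate)],
                            covariate)[[covariate]]
      fit_b <- tryCatch(
        suppressWarnings(suppressMessages(
          fit_extended_cox(perm, covariates, colony, ties))),
        error = function(e) NULL)
      if (!is.null(fit_b)) {
        beta_b <- fit_b$coefficients$beta[fit_b$coefficients$term ==
                                            covariate]
        if (abs(beta_b) <= 15) {
          null_stats[b] <-
            fit_b$coefficients$z[fit_b$coefficients$term == covariate]
        }
      }
    }
  }
  ok <- !is.na(null_stats)
  n_failed <- sum(!ok)
  nulls <- null_stats[ok]
  extreme <- switch(tail,
    two_sided = sum(abs(nulls) >= abs(z_obs)),
    lower = sum(nulls <= z_obs),
    upper = sum(nulls >= z_obs))
  p <- (1 + extreme) / (1 + length(nulls))
  unreliable <- n_failed > 0.05 * B
  if (unreliable) {
    warn(paste0(n_failed, " of ", B,
                " permutation refits failed (>5%); p-value unreliable"))
  }
  structure(list(
    observed = observed, covariate = covariate, observed_stat = z_obs,
    null_stats = nulls, B = B, B_ok = length(nulls), n_failed = n_failed,
    p_value = p, tail = tail, seed = as.integer(seed),
    n = observed$n_rows, unreliable = unreliable
  ), class = "qap_cox")
}

#' @export
print.qap_cox <- function(x, ...) {
  cat(sprintf(
    "<qap_cox> %s: z = %.3f, n = %d, p = %.4g (%s, B = %d, seed = %d)%s\n",
    x$covariate, x$observed_stat, x$n, x$p_value, x$tail, x$B_ok, x$seed,
    if (x$unreliable) " [UNRELIABLE: >5% refits failed]" else ""))
  invisible(x)
}

#' @method tidy qap_cox
#' @export
tidy.qap_cox <- function(x, ...) {
  tibble(term = x$covariate, statistic = x$observed_stat,
         p.value = x$p_value, tail = x$tail, B = x$B_ok, n = x$n)
}

#' @method glance qap_cox
#' @export
glance.qap_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$observed$n_events, B = x$B,
         B_ok = x$B_ok, n_failed = x$n_failed, seed = x$seed,
         unreliable = x$unreliable,
         null_mean = mean(x$null_stats), null_sd = sd(x$null_stats))
}

#' Survival curves by the product-limit (Kaplan-Meier) method
#'
#' Without a fitted model, returns the raw Kaplan-Meier estimate for the
#' records (optionally a subgroup). Given an [fit_extended_cox()] fit and
#' one or more covariate profiles, returns the model-based survival curve
#' for a subject holding those covariate values fixed — e.g. the
#' conventional low / medium / high resource-flow profiles at normalised
#' betweenness 0.1, 0.5 and 0.9.
#'
#' @param records Counting-process records.
#' @param fit Optional `nf_cox` fit.
#' @param profiles Data frame of covariate profiles (one row per curve);
#'   required with `fit`. A `label` column, if present, names the curves.
#' @return Tibble (`profile`, `time`, `survival`): `S(0) = 1` and each
#'   curve is nonincreasing in `[0, 1]`.
#' @examples
#' recs <- tibble::tibble(subject_id = letters[1:4], colony_id = "c",
#'                        start = 0, stop = c(1, 2, 3, 3),
#'                        event = c(1, 1, 0, 0))
#' survival_curve(recs)  # S = 1, 0.75, 0.50, 0.50 at t = 0..3
#' @export
survival_curve <- function(records, fit = NULL, profiles = NULL) {
  if (is.null(fit)) {
    sf <- survival::survfit(
      survival::Surv(start, stop, event) ~ 1, data = records)
    return(tibble(profile = "all",
                  time = c(0, sf$time),
                  survival = c(1, sf$surv)))
  }
  stopifnot(inherits(fit, "nf_cox"))
  if (is.null(profiles)) abort("profiles are required for model-based curves")
  profiles <- as_tibble(profiles)
  labels <- profiles$label %||%
    vapply(seq_len(nrow(profiles)), function(i) {
      paste(names(profiles), unlist(profiles[i, ]), sep = "=",
            collapse = ", ")
    }, character(1))
  profiles$label <- NULL
  dat <- fit$data
  purrr::map(seq_len(nrow(profiles)), function(i) {
    nd <- profiles[i, , drop = FALSE]
    # unspecified model terms are held at a reference value
    for (cv in setdiff(fit$spec$covariates, names(nd))) {
      nd[[cv]] <- stats::median(dat[[cv]], na.rm = TRUE)
    }
    if (!"colony_id" %in% names(nd)) {
      nd$colony_id <- sort(unique(dat$colony_id))[1]
    }
    sf <- survival::survfit(fit$fit, newdata = as.data.frame(nd))
    tibble(profile = labels[i], time = c(0, sf$time),
           survival = c(1, as.numeric(sf$surv)))
  }) |> bind_rows()
}
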