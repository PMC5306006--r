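#' Assemble the budding (founder-status) dataset
#'
#' One row per established nest per interval in which founding could have
#' been observed, labelled founder / possible_founder / nonfounder by
#' [classify_founders()]. Newly founded nests themselves are not rows:
#' they cannot have founded anything in the interval of their own
#' appearance.
#'
#' Covariate timing matters for a network measure. With
#' `timing = "start"` (the default) covariates are measured at the map
#' that opens the founding interval and `d_*` changes span the preceding
#' interval, so predictors are measured before the response they predict.
#' With `timing = "end"` covariates come from the map in which the new
#' nests appear and `d_*` spans the founding interval itself; that
#' convention reads naturally ("the change over the period in which the
#' nest was founded") but is mechanically confounded, because founding
#' adds a trail to the founder and thereby raises its betweenness in the
#' end map.
#'
#' @param ts A [colony_timeseries()] or list of them.
#' @param metrics Optional stacked [colony_metrics()] rows.
#' @param timing `"start"` (default) or `"end"`; see Details.
#' @return Tibble with `colony_id`, `timepoint`, `season`, `interval`,
#'   `nest_id` (persistent track id), `status`, covariates
#'   (`betweenness`, `size`, `canopy`, `tree_dist`, `wf_ratio`) and
#'   interval changes (`d_betweenness`, `d_size`, `d_wf_ratio`; `NA` for
#'   nests first seen at the interval's end).
#' @export
build_budding_data <- function(ts, metrics = NULL,
                               timing = c("start", "end")) {
  timing <- match.arg(timing)
  if (inherits(ts, "colony_timeseries")) ts <- list(ts)
  stopifnot(all(vapply(ts, inherits, TRUE, "colony_timeseries")))
  if (is.null(metrics)) {
    metrics <- bind_rows(purrr::map(ts, function(s) {
      bind_rows(purrr::map(s$maps, colony_metrics))
    }))
  }
  bind_rows(purrr::map(ts, budding_one, metrics = metrics,
                       timing = timing))
}

budding_one <- function(ts, metrics, timing = "start") {
  T_ <- length(ts$maps)
  if (T_ < 2L) return(tibble())
  events <- extract_events(ts)
  tps <- vapply(ts$maps, `[[`, "", "timepoint")
  met_at <- function(k) {  # k = 0-based map index
    metrics[metrics$colony_id == ts$colony_id &
              metrics$timepoint == tps[k + 1L], , drop = FALSE]
  }
  node_at <- function(track, k) {
    trk <- ts$tracks[ts$tracks$map_index == k, , drop = FALSE]
    trk$node_id[match(track, trk$track_id)]
  }
  purrr::map(seq_len(T_ - 1L), function(t) {
    j <- t - 1L  # interval index: founding between maps j and j+1
    m1 <- ts$maps[[t + 1L]]
    new <- events$node_id[events$interval == j & events$event == "founded"]
    labels <- classify_founders(m1, new)
    est <- labels |> filter(.data$status != "newly_founded")
    trk1 <- ts$tracks[ts$tracks$map_index == j + 1L, , drop = FALSE]
    tracks <- trk1$track_id[match(est$node_id, trk1$node_id)]
    val <- function(tbl, ids, col) tbl[[col]][match(ids, tbl$node_id)]
    if (timing == "end") {
      met_c <- met_at(j + 1L); ids_c <- est$node_id
      met_p <- met_at(j); ids_p <- node_at(tracks, j)
      tp_label <- m1$timepoint
    } else {
      met_c <- met_at(j); ids_c <- node_at(tracks, j)
      if (j >= 1L) {
        met_p <- met_at(j - 1L); ids_p <- node_at(tracks, j - 1L)
      } else {
        met_p <- NULL; ids_p <- NULL
      }
      tp_label <- tps[t]
    }
    d_of <- function(col) {
      if (is.null(met_p)) {
        rep(NA_real_, length(ids_c))
      } else {
        val(met_c, ids_c, col) - val(met_p, ids_p, col)
      }
    }
    wf_c <- met_c$wf_ratio[1] %||% NA_real_
    wf_p <- if (is.null(met_p)) NA_real_ else met_p$wf_ratio[1] %||% NA_real_
    tibble(
      colony_id = ts$colony_id,
      timepoint = tp_label,
      season = timepoint_season(m1$timepoint),
      interval = j,
      nest_id = paste0(ts$colony_id, ":", tracks),
      node_id = est$node_id,
      status = est$status,
      betweenness = val(met_c, ids_c, "norm_betweenness"),
      size = val(met_c, ids_c, "population"),
      canopy = val(met_c, ids_c, "canopy_cover"),
      tree_dist = val(met_c, ids_c, "tree_distance_m"),
      wf_ratio = wf_c,
      d_betweenness = d_of("norm_betweenness"),
      d_size = d_of("population"),
      d_wf_ratio = wf_c - wf_p
    )
  }) |> bind_rows()
}

#' Resolve the possible-founder policy on a budding table
#'
#' Applies one of the three codings of ambiguous founder attributions:
#' `"exclude"` drops `possible_founder` rows, `"as_founder"` and
#' `"as_nonfounder"` recode them. Adds a logical `founder` response
#' column.
#'
#' @param data A budding table from [build_budding_data()].
#' @param policy One of `"exclude"`, `"as_founder"`, `"as_nonfounder"`.
#' @return The table with a `founder` column, filtered per the policy.
#' @export
resolve_policy <- function(data, policy) {
  switch(policy,
    exclude = data |> filter(.data$status != "possible_founder") |>
      mutate(founder = as.integer(.data$status == "founder")),
    as_founder = data |>
      mutate(founder = as.integer(.data$status %in%
                                    c("founder", "possible_founder"))),
    as_nonfounder = data |>
      mutate(founder = as.integer(.data$status == "founder")))
}

#' Binomial mixed model for founder status
#'
#' Fits a binomial-logit GLMM of founder status (founder = 1,
#' nonfounder = 0) on the fixed effect(s) of interest, with random
#' intercepts for colony, nest identity and season. Possible founders —
#' nests whose credit for a new nest cannot be resolved — are excluded by
#' default, or coded to either class via `policy`. The optimiser is
#' pinned (bobyqa) so refits are deterministic.
#'
#' @param data A [build_budding_data()] table.
#' @param fixed_effect Character vector of fixed-effect terms (model
#'   formula syntax, e.g. `"betweenness"` or `"flow_category"`).
#' @param policy `"exclude"` (default), `"as_founder"` or
#'   `"as_nonfounder"` for possible-founder rows.
#' @return An `nf_glmm`: list with the [lme4::glmer()] `fit`, the rows
#'   used (`data`), `fixed_effect`, `policy`, `n` and a `boundary` flag
#'   (`TRUE` when a variance component was estimated at 0).
#' @export
fit_founder_glmm <- function(data, fixed_effect,
                             policy = c("exclude", "as_founder",
                                        "as_nonfounder")) {
  policy <- match.arg(policy)
  dat <- resolve_policy(data, policy)
  vars <- intersect(all.vars(stats::as.formula(
    paste("~", paste(fixed_effect, collapse = "+")))), names(dat))
  dat <- dat[stats::complete.cases(dat[, vars, drop = FALSE]), , drop = FALSE]
  if (length(unique(dat$founder)) < 2L) {
    abort("degenerate response: founder status has a single class")
  }
  for (v in vars) {
    if (length(unique(dat[[v]])) < 2L) {
      abort(paste0("singular design: fixed effect is constant: ", v))
    }
  }
  if (length(unique(dat$colony_id)) < 2L) {
    abort("at least two colonies are required for the colony random effect")
  }
  fml <- stats::as.formula(paste(
    "founder ~", paste(fixed_effect, collapse = " + "),
    "+ (1 | colony_id) + (1 | nest_id) + (1 | season)"))
  fit <- suppressMessages(lme4::glmer(
    fml, data = dat, family = stats::binomial("logit"),
    control = lme4::glmerControl(optimizer = "bobyqa",
                                 calc.derivs = FALSE,
                                 check.conv.singular = "ignore")))
  structure(list(fit = fit, data = dat, fixed_effect = fixed_effect,
                 policy = policy, n = nrow(dat),
                 boundary = lme4::isSingular(fit, tol = 1e-5)),
            class = "nf_glmm")
}

#' @export
print.nf_glmm <- function(x, ...) {
  cat(sprintf("<nf_glmm> founder ~ %s (policy: %s, n = %d%s)\n",
              paste(x$fixed_effect, collapse = " + "), x$policy, x$n,
              if (x$boundary) ", variance at boundary" else ""))
  print(lme4::fixef(x$fit))
  invisible(x)
}

#' @method tidy nf_glmm
#' @export
tidy.nf_glmm <- function(x, ...) {
  fe <- lme4::fixef(x$fit)
  se <- sqrt(diag(as.matrix(vcov(x$fit))))
  tibble(term = names(fe), estimate = unname(fe), std.error = unname(se),
         statistic = unname(fe / se))
}

#' Chi-squared analysis of deviance for a fitted founder model
#'
#' Compares the full model against the null model stripped of its fixed
#' effect (same rows, same random effects):
#' `chisq = 2 (logLik_full - logLik_null)` referred to the chi-squared
#' distribution with df equal to the difference in fixed-effect parameter
#' count. A significant difference means the fixed effect explains
#' founder status.
#'
#' @param full An `nf_glmm` from [fit_founder_glmm()].
#' @param null Optional `nf_glmm` null model; fitted automatically (an
#'   intercept-only model on the same rows) when omitted.
#' @return An `nf_aod`: tibble row (`fixed_effect`, `chisq`, `df`, `p`,
#'   `n`, `policy`).
#' @export
analysis_of_deviance <- function(full, null = NULL) {
  stopifnot(inherits(full, "nf_glmm"))
  if (is.null(null)) {
    fml0 <- founder ~ (1 | colony_id) + (1 | nest_id) + (1 | season)
    fit0 <- suppressMessages(lme4::glmer(
      fml0, data = full$data, family = stats::binomial("logit"),
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   calc.derivs = FALSE,
                                   check.conv.singular = "ignore")))
    ll0 <- as.numeric(logLik(fit0))
    df0 <- 1L
  } else {
    stopifnot(inherits(null, "nf_glmm"))
    if (null$n != full$n ||
        !identical(sort(paste(null$data$nest_id, null$data$interval)),
                   sort(paste(full$data$nest_id, full$data$interval)))) {
      abort("incomparable models: full and null were fitted on different rows")
    }
    ll0 <- as.numeric(logLik(null$fit))
    df0 <- length(lme4::fixef(null$fit))
  }
  ll1 <- as.numeric(logLik(full$fit))
  chisq <- 2 * (ll1 - ll0)
  df <- length(lme4::fixef(full$fit)) - df0
  if (df < 1L) abort("null model must be nested with fewer fixed effects")
  out <- tibble(fixed_effect = paste(full$fixed_effect, collapse = " + "),
                chisq = chisq, df = df,
                p = stats::pchisq(pmax(chisq, 0), df, lower.tail = FALSE),
                n = full$n, policy = full$policy)
  class(out) <- c("nf_aod", class(out))
  out
}

#' One-call founder test: GLMM fit plus analysis of deviance
#'
#' @inheritParams fit_founder_glmm
#' @return The `nf_aod` row for the fixed effect.
#' @export
founder_aod <- function(data, fixed_effect,
                        policy = c("exclude", "as_founder",
                                   "as_nonfounder")) {
  policy <- match.arg(policy)
  analysis_of_deviance(fit_founder_glmm(data, fixed_effect, policy))
}

#' Possible-founder policy sensitivity
#'
#' Runs the founder analysis of deviance under all three
#' possible-founder codings and reports whether the qualitative
#' conclusion (p below `alpha`) is stable across them.
#'
#' @inheritParams fit_founder_glmm
#' @param alpha Significance threshold for the stability check.
#' @return Tibble of the three `nf_aod` rows plus a `policy_stable`
#'   attribute (`TRUE` when all three agree on significance).
#' @export
policy_sensitivity <- function(data, fixed_effect, alpha = 0.05) {
  res <- bind_rows(purrr::map(
    c("exclude", "as_founder", "as_nonfounder"),
    function(p) founder_aod(data, fixed_effect, p)))
  attr(res, "policy_stable") <- length(unique(res$p < alpha)) == 1L
  res
}
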