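#' @title Protected-vs-control comparison by propensity-score matching
#' @description
#' Cells are labelled treated (protected-area overlap > 50%), control
#' (< 5%) or excluded (marginal protection). Within each biogeographic
#' region a logistic propensity model (main effects on standardized
#' covariates) is fitted, treated cells are matched to unused controls by
#' nearest propensity (greedy, hardest-to-match first) under a caliper of
#' 0.25 SD of the scores, balance is diagnosed with standardized mean
#' differences (balance at SMD <= 0.1) and the C-statistic, and outcomes
#' are compared with a paired Wilcoxon signed-rank test.
#' @name matching
NULL

#' Three-way treatment labels from protection fractions
#'
#' `treated` above 0.5, `control` below 0.05, `excluded` in between
#' (both boundaries fall into `excluded`).
#'
#' @param fraction Numeric vector or matrix of protected fractions in
#'   `[0, 1]`.
#' @return Character vector (or matrix) of labels.
#' @examples
#' assign_treatment(c(0.6, 0.2, 0.01))  # treated excluded control
#' @export
assign_treatment <- function(fraction) {
  if (any(!is.na(fraction) & (fraction < 0 | fraction > 1)))
    stop("protection fractions must lie in [0, 1]")
  out <- ifelse(fraction > 0.5, "treated",
                ifelse(fraction < 0.05, "control", "excluded"))
  if (is.matrix(fraction)) dim(out) <- dim(fraction)
  out
}

standardize_columns <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  Xs <- sweep(X, 2, mu, "-")
  nz <- sds > 0
  Xs[, nz] <- sweep(Xs[, nz, drop = FALSE], 2, sds[nz], "/")
  Xs[, !nz] <- 0  # constant covariates carry no information
  Xs
}

#' Propensity scores from a main-effects logistic model
#'
#' Covariates are standardized (mean 0, SD 1 within the supplied sample;
#' constant columns drop out) and a logit-link treatment model with main
#' effects is fitted. Perfect separation - the model can classify treatment
#' exactly, so no comparable controls exist - is an error advising
#' covariate reduction.
#'
#' @param covariates Data frame or matrix of cell covariates.
#' @param treatment Logical vector (or `"treated"`/`"control"` labels),
#'   with at least one treated and one control unit.
#' @return Numeric vector of fitted treatment probabilities in (0, 1).
#' @export
propensity_scores <- function(covariates, treatment) {
  if (is.character(treatment)) treatment <- treatment == "treated"
  treatment <- as.logical(treatment)
  if (!any(treatment) || all(treatment))
    stop("need at least one treated and one control unit")
  Xs <- standardize_columns(covariates)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, Xs), treatment * 1,
                   family = stats::binomial()))
  p <- fit$fitted.values
  if (fit$deviance < 1e-6 || all(p[treatment] > 1 - 1e-8) && all(p[!treatment] < 1e-8))
    stop("perfect separation in the propensity model; reduce the covariate set")
  p
}

#' Nearest-neighbour matching without replacement
#'
#' Within each region, treated units are processed in descending propensity
#' (hardest to match first; ties by id) and each takes the still-unused
#' control with the nearest score. Pairs whose score distance exceeds
#' `caliper_sd` times the SD of the region's scores are discarded. Ties at
#' equal distance break deterministically by smaller control id. Regions
#' lacking controls (or treated units) are skipped with a warning.
#'
#' @param scores Propensity scores for all units.
#' @param treatment Logical or label vector parallel to `scores`;
#'   `"excluded"` units are ignored.
#' @param region Region label per unit (default one region).
#' @param ids Unit identifiers (default sequence).
#' @param caliper_sd Caliper in SD-of-scores units (default 0.25).
#' @return A `matched_pairs` object: data frame `pairs` (`treated_id`,
#'   `control_id`, `region`, `distance`), per-region `caliper_used` (on the
#'   score scale), and `discarded` counts of unmatched treated units.
#' @export
nn_match <- function(scores, treatment, region = "all",
                     ids = seq_along(scores), caliper_sd = 0.25) {
  if (is.logical(treatment)) treatment <- ifelse(treatment, "treated", "control")
  region <- rep_len(as.character(region), length(scores))
  stopifnot(length(treatment) == length(scores), length(ids) == length(scores),
            caliper_sd > 0)
  pairs <- list(); calipers <- c(); discarded <- c()
  for (rg in unique(region)) {
    in_rg <- region == rg & treatment %in% c("treated", "control")
    tr <- in_rg & treatment == "treated"
    co <- in_rg & treatment == "control"
    if (!any(tr) || !any(co)) {
      warning(sprintf("region '%s' lacks %s units; skipped", rg,
                      if (!any(co)) "control" else "treated"))
      next
    }
    cal <- caliper_sd * stats::sd(scores[in_rg])
    if (is.na(cal) || cal == 0) cal <- caliper_sd  # degenerate score spread
    ord <- order(-scores[tr], ids[tr])
    t_ids <- ids[tr][ord]; t_scores <- scores[tr][ord]
    res <- nn_match_cpp(t_scores, scores[co], as.integer(ids[co]), cal)
    ok <- !is.na(res$control_id)
    pairs[[rg]] <- data.frame(treated_id = t_ids[ok],
                              control_id = res$control_id[ok],
                              region = rep(rg, sum(ok)),
                              distance = res$distance[ok],
                              stringsAsFactors = FALSE)
    calipers[rg] <- cal
    discarded[rg] <- sum(!ok)
  }
  structure(list(pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))),
                 caliper_used = calipers, caliper_sd = caliper_sd,
                 discarded = discarded),
            class = "matched_pairs")
}

#' @export
print.matched_pairs <- function(x, ...) {
  np <- if (is.null(x$pairs)) 0L else nrow(x$pairs)
  cat(sprintf("<matched_pairs> %d pairs across %d region(s); %d treated discarded (caliper %.3g SD)\n",
              np, length(x$caliper_used), sum(x$discarded), x$caliper_sd))
  invisible(x)
}

#' Standardized mean difference of one covariate
#'
#' `|mean_T - mean_C| / sqrt((var_T + var_C) / 2)`; values at or below 0.1
#' indicate acceptable balance. A zero pooled variance with unequal means
#' yields `Inf` (flagged unbalanced); with equal means the SMD is 0.
#'
#' @param x Covariate values.
#' @param treatment Logical or label vector (each group needs >= 2 units).
#' @return The SMD (non-negative scalar) with attribute `balanced`.
#' @export
balance_smd <- function(x, treatment) {
  if (is.character(treatment)) treatment <- treatment == "treated"
  xt <- x[treatment]; xc <- x[!treatment]
  if (length(xt) < 2L || length(xc) < 2L)
    stop("need at least 2 units per group for an SMD")
  pooled <- sqrt((stats::var(xt) + stats::var(xc)) / 2)
  md <- abs(mean(xt) - mean(xc))
  smd <- if (pooled == 0) (if (md == 0) 0 else Inf) else md / pooled
  attr(smd, "balanced") <- smd <= 0.1
  smd
}

#' C-statistic (concordance of scores with treatment)
#'
#' Rank-based AUC of the propensity scores against treatment status, folded
#' at 0.5 so the minimum 0.5 means the model cannot discriminate the groups
#' (the post-matching ideal) and 1 means perfect separation. Ties receive
#' mid-ranks.
#'
#' @param scores Propensity scores.
#' @param treatment Logical or label vector; both groups non-empty.
#' @return A value in `[0.5, 1]`.
#' @export
c_statistic <- function(scores, treatment) {
  if (is.character(treatment)) treatment <- treatment == "treated"
  nt <- sum(treatment); nc <- sum(!treatment)
  if (nt == 0L || nc == 0L) stop("both groups must be non-empty")
  r <- rank(scores)
  auc <- (sum(r[treatment]) - nt * (nt + 1) / 2) / (nt * nc)
  max(auc, 1 - auc)
}

#' Paired Wilcoxon signed-rank test on matched outcomes
#'
#' Tests whether matched treated and control cells differ in an exposure
#' metric. Zero differences are dropped; with up to 25 informative pairs
#' the exact signed-rank null is used (falling back to the tie-corrected
#' normal approximation when ties make the exact distribution unavailable),
#' above that the normal approximation with tie correction.
#'
#' @param outcomes_treated,outcomes_control Outcome values of the matched
#'   treated and control units (pair-aligned).
#' @param alternative Passed to [stats::wilcox.test()] (default two-sided).
#' @return A list: `statistic` (V), `p_value`, `n_pairs` (informative
#'   pairs), `n_zero` (dropped zero differences), `degenerate` (`TRUE` with
#'   `p_value = 1` when all differences are zero).
#' @export
paired_wilcoxon <- function(outcomes_treated, outcomes_control,
                            alternative = "two.sided") {
  stopifnot(length(outcomes_treated) == length(outcomes_control))
  d <- outcomes_treated - outcomes_control
  d <- d[!is.na(d)]
  if (!length(d)) stop("no complete pairs")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = NA_real_, p_value = 1, n_pairs = 0L,
                n_zero = n_zero, degenerate = TRUE))
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = length(d) <= 25, correct = TRUE,
                       alternative = alternative))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = length(d), n_zero = n_zero, degenerate = FALSE)
}

#' Full matching analysis with balance diagnostics
#'
#' Runs the complete protected-vs-control comparison on a cell table:
#' treatment assignment from protection fractions, per-region propensity
#' models, nearest-neighbour matching, pre/post SMD per covariate,
#' C-statistic before and after matching (both on the original scores and
#' on scores refitted within the matched sample), and paired Wilcoxon tests
#' per outcome metric and region.
#'
#' @param cells Data frame with columns `cell_id`, `region`,
#'   `protection_fraction`, the covariates and the outcome metrics.
#' @param covariate_names Names of the covariate columns.
#' @param outcome_names Names of the outcome metric columns.
#' @param caliper_sd Caliper in SD-of-scores units (default 0.25).
#' @return A `match_report` list: `pairs`, `balance` (covariate x region
#'   SMD before/after), `c_statistic` (per region, before / after-refit /
#'   after-original), `wilcoxon` (per outcome x region), `discarded`,
#'   `n_treated`, `n_control`.
#' @export
match_report <- function(cells, covariate_names, outcome_names,
                         caliper_sd = 0.25) {
  stopifnot(all(c("cell_id", "region", "protection_fraction") %in% names(cells)),
            all(covariate_names %in% names(cells)),
            all(outcome_names %in% names(cells)))
  cells$treatment <- assign_treatment(cells$protection_fraction)
  keep <- cells$treatment != "excluded"
  balance <- list(); cstats <- list(); wilcox <- list()
  all_pairs <- list(); discarded <- c()
  for (rg in unique(cells$region)) {
    sub <- cells[keep & cells$region == rg, , drop = FALSE]
    tr <- sub$treatment == "treated"
    if (sum(tr) < 2L || sum(!tr) < 2L) {
      warning(sprintf("region '%s' lacks enough treated/control cells; skipped", rg))
      next
    }
    scores <- propensity_scores(sub[covariate_names], tr)
    m <- nn_match(scores, tr, region = rg, ids = sub$cell_id,
                  caliper_sd = caliper_sd)
    if (is.null(m$pairs) || !nrow(m$pairs)) {
      warning(sprintf("region '%s': no pairs within the caliper; skipped", rg))
      next
    }
    all_pairs[[rg]] <- m$pairs
    discarded[rg] <- unname(m$discarded)
    it <- match(m$pairs$treated_id, sub$cell_id)
    ic <- match(m$pairs$control_id, sub$cell_id)
    balance[[rg]] <- data.frame(
      region = rg, covariate = covariate_names,
      smd_before = vapply(covariate_names, function(v)
        as.numeric(balance_smd(sub[[v]], tr)), numeric(1)),
      smd_after = vapply(covariate_names, function(v)
        as.numeric(balance_smd(c(sub[[v]][it], sub[[v]][ic]),
                               rep(c(TRUE, FALSE), each = nrow(m$pairs)))),
        numeric(1)),
      stringsAsFactors = FALSE)
    balance[[rg]]$balanced_after <- balance[[rg]]$smd_after <= 0.1
    matched_idx <- c(it, ic)
    matched_tr <- rep(c(TRUE, FALSE), each = nrow(m$pairs))
    refit <- tryCatch(
      propensity_scores(sub[matched_idx, covariate_names, drop = FALSE], matched_tr),
      error = function(e) rep(NA_real_, length(matched_idx)))
    cstats[[rg]] <- data.frame(
      region = rg,
      c_before = c_statistic(scores, tr),
      c_after_refit = if (anyNA(refit)) NA_real_ else c_statistic(refit, matched_tr),
      c_after_original = c_statistic(scores[matched_idx], matched_tr),
      n_pairs = nrow(m$pairs), stringsAsFactors = FALSE)
    wilcox[[rg]] <- do.call(rbind, lapply(outcome_names, function(oc) {
      complete <- !is.na(sub[[oc]][it]) & !is.na(sub[[oc]][ic])
      if (!any(complete)) {
        warning(sprintf("region '%s': outcome '%s' has no complete matched pairs",
                        rg, oc))
        return(data.frame(region = rg, outcome = oc, statistic = NA_real_,
                          p_value = NA_real_, n_pairs = 0L,
                          median_difference = NA_real_,
                          stringsAsFactors = FALSE))
      }
      wt <- paired_wilcoxon(sub[[oc]][it], sub[[oc]][ic])
      data.frame(region = rg, outcome = oc, statistic = wt$statistic,
                 p_value = wt$p_value, n_pairs = wt$n_pairs,
                 median_difference = stats::median(sub[[oc]][it] - sub[[oc]][ic],
                                                  na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!length(all_pairs)) stop("no region produced matched pairs")
  structure(list(
    pairs = do.call(rbind, c(unname(all_pairs), list(make.row.names = FALSE))),
    balance = do.call(rbind, c(unname(balance), list(make.row.names = FALSE))),
    c_statistic = do.call(rbind, c(unname(cstats), list(make.row.names = FALSE))),
    wilcoxon = do.call(rbind, c(unname(wilcox), list(make.row.names = FALSE))),
    discarded = discarded,
    n_treated = sum(keep & cells$treatment == "treated"),
    n_control = sum(keep & cells$treatment == "control"),
    caliper_sd = caliper_sd),
    class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d pairs (%d treated, %d control cells; %d discarded)\n",
              nrow(x$pairs), x$n_treated, x$n_control, sum(x$discarded)))
  cat(sprintf("  C-statistic before %.3f -> after (refit) %.3f; max SMD after %.3f\n",
              mean(x$c_statistic$c_before), mean(x$c_statistic$c_after_refit),
              max(x$balance$smd_after)))
  invisible(x)
}
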