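# pooled-variance two-sample t statistic
t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Permutation-based two-sample t test
#'
#' The observed statistic is the pooled-variance two-sample t; the null is
#' built by randomly reassigning group labels (group sizes preserved)
#' `n_perm` times. Two-sided p with the +1 finite-sample correction:
#' `p = (1 + #\{|t_perm| >= |t_obs|\}) / (n_perm + 1)`, so p is never 0 and
#' never below `1/(n_perm + 1)`. Missing values are dropped per group.
#'
#' @param values_a,values_b numeric vectors (NA allowed, dropped)
#' @param n_perm number of permutations
#' @param seed RNG seed
#' @return list: p_value, statistic, n_a, n_b
#' @export
permutation_two_sample <- function(values_a, values_b, n_perm = 10000L,
                                   seed = 1L) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("insufficient data: need >= 2 non-missing values per group",
         call. = FALSE)
  }
  t_obs <- t_pooled(a, b)
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  # sums-based t for speed: per permutation only the group-A index set moves
  tot <- sum(pool); tot2 <- sum(pool^2)
  nb <- n - na
  t_perm <- vapply(seq_len(n_perm), function(i) {
    ia <- sample.int(n, na)
    sa <- sum(pool[ia]); sa2 <- sum(pool[ia]^2)
    ma <- sa / na; mb <- (tot - sa) / nb
    va <- (sa2 - na * ma^2) / (na - 1)
    vb <- ((tot2 - sa2) - nb * mb^2) / (nb - 1)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (n - 2)
    (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  }, numeric(1))
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
  list(p_value = p, statistic = t_obs, n_a = na, n_b = nb)
}

#' Bonferroni-corrected significance threshold for one partition model
#'
#' Each partition into k states entails k hypotheses per metric, so the
#' threshold is `alpha / k`.
#'
#' @param alpha nominal level
#' @param k number of states in the partition
#' @return corrected alpha
#' @export
bonferroni_threshold <- function(alpha = 0.05, k) {
  stopifnot(k >= 1)
  alpha / k
}

#' Hedges' g effect size
#'
#' Standardized mean difference with the small-sample correction factor
#' `1 - 3 / (4 (n_a + n_b) - 9)`.
#'
#' @param values_a,values_b numeric vectors (NA dropped)
#' @return g (positive when group A exceeds group B)
#' @export
hedges_g <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("insufficient data for an effect size", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("undefined effect size: zero pooled SD", call. = FALSE)
  d <- (mean(a) - mean(b)) / sp
  d * (1 - 3 / (4 * (na + nb) - 9))
}

#' Paired permutation test (within-group, two conditions)
#'
#' Statistic: mean per-subject difference `cond1 - cond2`. Null: random
#' per-subject sign flips. Two-sided p with the +1 correction. Incomplete
#' pairs are dropped.
#'
#' @param values_cond1,values_cond2 per-subject values, aligned
#' @param n_perm number of sign-flip draws
#' @param seed RNG seed
#' @return list: p_value, statistic (mean difference), n
#' @export
paired_permutation_within <- function(values_cond1, values_cond2,
                                      n_perm = 10000L, seed = 1L) {
  stopifnot(length(values_cond1) == length(values_cond2))
  d <- values_cond1 - values_cond2
  d <- sort(d[!is.na(d)])  # order-invariant: the statistic depends only on the multiset
  if (length(d) < 2L) {
    stop("insufficient data: need >= 2 complete pairs", call. = FALSE)
  }
  obs <- mean(d)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  m <- length(d)
  stat <- vapply(seq_len(n_perm), function(i) {
    mean(d * sample(c(-1, 1), m, replace = TRUE))
  }, numeric(1))
  p <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(p_value = p, statistic = obs, n = m)
}

#' Covariate-adjusted group test (OLS + Freedman-Lane permutation)
#'
#' Ordinary least squares of the metric on a group indicator plus a numeric
#' covariate. The primary p-value is a Freedman-Lane permutation p for the
#' group coefficient (residuals of the covariate-only model are permuted and
#' added back to its fitted values); the classical two-sided t-test p is
#' reported alongside.
#'
#' @param metric numeric response
#' @param group two-level factor/character/logical
#' @param covariate numeric covariate
#' @param n_perm permutations
#' @param seed RNG seed
#' @return list: p_perm (primary), p_classical, coefficient (group effect), n
#' @export
covariate_adjusted_test <- function(metric, group, covariate,
                                    n_perm = 10000L, seed = 1L) {
  ok <- stats::complete.cases(metric, group, covariate)
  y <- metric[ok]
  g <- factor(group[ok])
  x <- covariate[ok]
  if (length(y) < 4L) stop("insufficient complete cases (< 4)", call. = FALSE)
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
  gnum <- as.numeric(g == levels(g)[1L])
  if (stats::sd(stats::resid(stats::lm(gnum ~ x))) < 1e-12) {
    stop("degenerate design: group is collinear with the covariate",
         call. = FALSE)
  }
  full <- stats::lm(y ~ g + x)
  sm <- summary(full)$coefficients
  t_obs <- sm[2L, "t value"]
  p_classical <- sm[2L, "Pr(>|t|)"]
  reduced <- stats::lm(y ~ x)
  fit0 <- stats::fitted(reduced)
  res0 <- stats::resid(reduced)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- length(y)
  t_perm <- vapply(seq_len(n_perm), function(i) {
    ystar <- fit0 + res0[sample.int(n)]
    summary(stats::lm(ystar ~ g + x))$coefficients[2L, "t value"]
  }, numeric(1))
  p_perm <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
  list(p_perm = p_perm, p_classical = p_classical,
       coefficient = stats::coef(full)[2L], n = n)
}

#' Group-by-condition interaction test
#'
#' Statistic: between-group difference of the per-subject condition change
#' (`cond2 - cond1`). Inference by permuting group labels over subjects. The
#' classical repeated-measures ANOVA interaction F (via `stats::aov` with a
#' subject error stratum) is reported alongside for reference. Subjects
#' missing a condition are dropped with a warning.
#'
#' @param values_cond1,values_cond2 per-subject values, aligned
#' @param group per-subject group labels (2 levels)
#' @param n_perm permutations
#' @param seed RNG seed
#' @return list: p_value (permutation, primary), statistic, F_classical,
#'   p_classical, n_a, n_b
#' @export
group_by_condition_interaction <- function(values_cond1, values_cond2, group,
                                           n_perm = 10000L, seed = 1L) {
  stopifnot(length(values_cond1) == length(values_cond2),
            length(group) == length(values_cond1))
  ok <- stats::complete.cases(values_cond1, values_cond2, group)
  if (any(!ok)) {
    warning(sum(!ok), " subject(s) dropped: missing condition or group")
  }
  v1 <- values_cond1[ok]; v2 <- values_cond2[ok]
  g <- factor(group[ok])
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
  delta <- v2 - v1
  ga <- levels(g)[1L]
  obs <- mean(delta[g == ga]) - mean(delta[g != ga])
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- length(delta); na <- sum(g == ga)
  stat <- vapply(seq_len(n_perm), function(i) {
    ia <- sample.int(n, na)
    mean(delta[ia]) - mean(delta[-ia])
  }, numeric(1))
  p <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (n_perm + 1)
  # classical mixed ANOVA for reference
  long <- data.frame(y = c(v1, v2),
                     cond = factor(rep(c("c1", "c2"), each = n)),
                     grp = factor(rep(g, 2L)),
                     subj = factor(rep(seq_len(n), 2L)))
  av <- summary(stats::aov(y ~ grp * cond + Error(subj), data = long))
  within_tab <- av[["Error: Within"]][[1L]]
  row <- grep("grp:cond", rownames(within_tab))
  f_cl <- within_tab[row, "F value"]
  p_cl <- within_tab[row, "Pr(>F)"]
  list(p_value = p, statistic = obs, F_classical = f_cl, p_classical = p_cl,
       n_a = na, n_b = n - na)
}

# one two-sample comparison row
compare_one <- function(va, vb, n_perm, seed, k, state_id, metric_name,
                        condition, alpha) {
  pt <- permutation_two_sample(va, vb, n_perm = n_perm, seed = seed)
  g <- tryCatch(hedges_g(va, vb), error = function(e) NA_real_)
  a_corr <- bonferroni_threshold(alpha, k)
  data.frame(k = k, condition = condition, state_id = state_id,
             metric_name = metric_name,
             mean_a = mean(va, na.rm = TRUE), sem_a = sem(va),
             mean_b = mean(vb, na.rm = TRUE), sem_b = sem(vb),
             p_value = pt$p_value, effect_size_g = g,
             alpha_corrected = a_corr,
             significant_corrected = pt$p_value < a_corr,
             n_a = pt$n_a, n_b = pt$n_b, stringsAsFactors = FALSE)
}

#' Between-group comparisons across all partition models
#'
#' For each k, each condition and each state: permutation t tests on
#' occupancy probability and mean lifetime; per k and condition a test on
#' switching frequency; and, at `selected_k`, a test per off-diagonal
#' switching-matrix cell. Per-partition Bonferroni thresholds (`alpha / k`)
#' and Hedges' g are attached to every row. Also builds a consistency table:
#' the most significant (probability) state per k, with the centroid
#' correlation to the matched state at the neighbouring k.
#'
#' @param sample a `leida_eigen_sample` (provides the provenance index)
#' @param models list of `leida_partition` from [sweep_k()]
#' @param selected_k partition examined in depth for switching cells
#'   (NULL = skip)
#' @param n_perm permutations per test
#' @param alpha nominal level before correction
#' @param seed master seed (fans out per test deterministically)
#' @param include_truncated,conditional_on_switch metric options
#' @return list: `results` (one data.frame row per comparison),
#'   `consistency` (per k and condition the most significant state and its
#'   cross-k centroid correlation)
#' @export
compare_all <- function(sample, models, selected_k = NULL, n_perm = 10000L,
                        alpha = 0.05, seed = 1L, include_truncated = TRUE,
                        conditional_on_switch = TRUE) {
  idx <- sample$index
  conds <- unique(idx$condition)
  n_tests_max <- sum(vapply(models, function(m) m$k * 2L + 1L +
                              m$k * (m$k - 1L), numeric(1))) * length(conds)
  seeds <- derive_seeds(seed, n_tests_max)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }
  rows <- list()
  for (m in models) {
    tcs <- extract_timecourses(m, idx)
    met <- cohort_metrics(tcs, m$k, include_truncated = include_truncated,
                          conditional_on_switch = conditional_on_switch)
    for (cond in conds) {
      bs <- met$by_state[met$by_state$condition == cond, ]
      by_scan <- met$by_scan[met$by_scan$condition == cond, ]
      for (s in seq_len(m$k)) {
        sb <- bs[bs$state == s, ]
        va <- sb$probability[sb$group == "A"]
        vb <- sb$probability[sb$group == "B"]
        rows[[length(rows) + 1L]] <-
          compare_one(va, vb, n_perm, next_seed(), m$k, s, "probability",
                      cond, alpha)
        la <- sb$lifetime[sb$group == "A"]
        lb <- sb$lifetime[sb$group == "B"]
        rows[[length(rows) + 1L]] <- tryCatch(
          compare_one(la, lb, n_perm, next_seed(), m$k, s, "lifetime",
                      cond, alpha),
          error = function(e) NULL)
      }
      rows[[length(rows) + 1L]] <-
        compare_one(by_scan$switching_frequency[by_scan$group == "A"],
                    by_scan$switching_frequency[by_scan$group == "B"],
                    n_perm, next_seed(), m$k, NA_integer_,
                    "switching_frequency", cond, alpha)
      if (!is.null(selected_k) && m$k == selected_k) {
        sw <- met$switching[met$switching$condition == cond, ]
        for (s_from in seq_len(m$k)) {
          for (s_to in seq_len(m$k)) {
            if (s_from == s_to && conditional_on_switch) next
            cell <- sw[sw$from == s_from & sw$to == s_to, ]
            va <- cell$p[cell$group == "A"]
            vb <- cell$p[cell$group == "B"]
            res <- tryCatch(
              compare_one(va, vb, n_perm, next_seed(), m$k, s_from,
                          sprintf("transition(%d->%d)", s_from, s_to),
                          cond, alpha),
              error = function(e) NULL)
            if (!is.null(res)) rows[[length(rows) + 1L]] <- res
          }
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results,
       consistency = consistency_table(results, models))
}

#' Most significant state per partition with cross-k centroid correlation
#'
#' For each k and condition, the state with the smallest probability p-value;
#' `r_next` is the centroid correlation of that state with its best match in
#' the next partition of the sweep.
#'
#' @param results comparison rows from [compare_all()]
#' @param models the partition models
#' @return data.frame: k, condition, state_id, p_value,
#'   significant_corrected, r_next
#' @export
consistency_table <- function(results, models) {
  pr <- results[results$metric_name == "probability", ]
  ks <- sort(unique(pr$k))
  out <- list()
  for (cond in unique(pr$condition)) {
    for (i in seq_along(ks)) {
      kk <- ks[i]
      sub <- pr[pr$k == kk & pr$condition == cond, ]
      best <- sub[which.min(sub$p_value), ]
      r_next <- NA_real_
      if (i < length(ks)) {
        ma <- models[[paste0("k", kk)]]
        mb <- models[[paste0("k", ks[i + 1L])]]
        mm <- match_states(ma, mb)
        r_next <- mm$r[mm$state_a == best$state_id]
      }
      out[[length(out) + 1L]] <-
        data.frame(k = kk, condition = cond, state_id = best$state_id,
                   p_value = best$p_value,
                   significant_corrected = best$significant_corrected,
                   r_next = r_next, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
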