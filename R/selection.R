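# Within-site phenotypic selection analysis in the Lande-Arnold tradition:
# standardized selection differentials S = cov(w, z) with significance from
# the Pearson correlation, and directional selection gradients beta from the
# multiple regression of relative fitness on all standardized traits
# jointly. A companion check asks whether selection points toward the local
# community-weighted mean, the usual optimality interpretation of
# trait-gradient studies.

#' Relative fitness
#'
#' Divides each individual's fitness measure (here final dry biomass) by the
#' mean over the individuals supplied, so the returned values average to 1
#' exactly.
#'
#' @param W Numeric fitness measures, non-negative, at least two of them
#'   positive.
#' @return Vector `w = W / mean(W)`.
#' @examples
#' relative_fitness(c(2, 4, 6))  # 0.5 1.0 1.5
#' @export
relative_fitness <- function(W) {
  W <- as.numeric(W)
  if (anyNA(W)) .stopf("fitness values must be complete; filter NAs first")
  if (any(W < 0)) .stopf("fitness values must be non-negative")
  if (sum(W > 0) < 2) .stopf("need at least two individuals with positive fitness")
  W / mean(W)
}

#' Standardize traits to zero mean and unit variance
#'
#' Column-wise `z = (x - mean) / sd` with the sample (n-1) standard
#' deviation. Intended to be applied within a site; zero-variance columns
#' are an error naming the trait.
#'
#' @param X Numeric vector, matrix or data.frame of trait values.
#' @return Matrix of standardized traits (a vector input returns a
#'   one-column matrix).
#' @export
standardize_traits <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) .stopf("trait values must be complete; filter NAs first")
  sds <- apply(X, 2, sd)
  if (any(sds == 0 | is.na(sds)))
    .stopf("zero-variance trait(s): %s",
           paste(colnames(X)[sds == 0 | is.na(sds)] %||% which(sds == 0),
                 collapse = ", "))
  scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Standardized selection differential
#'
#' `S = cov(w, z)` (sample covariance, n-1 denominator) between relative
#' fitness and one standardized trait; total selection on the trait. The
#' two-sided p-value comes from the Pearson correlation test between the
#' two variables; it is `NA` when either variable is constant.
#'
#' @param w Relative fitness from [relative_fitness()].
#' @param z One standardized trait from [standardize_traits()].
#' @return List with elements `S` and `p`.
#' @export
selection_differential <- function(w, z) {
  if (length(w) != length(z)) .stopf("`w` and `z` must be paired")
  ok <- complete.cases(w, z)
  if (sum(ok) < 3) .stopf("need at least 3 complete pairs")
  w <- w[ok]; z <- z[ok]
  S <- cov(w, z)
  p <- if (sd(w) == 0 || sd(z) == 0) NA_real_ else
    suppressWarnings(cor.test(w, z)$p.value)
  list(S = S, p = p)
}

#' Directional selection gradients
#'
#' Partial regression coefficients of relative fitness on all standardized
#' traits jointly (ordinary least squares with intercept): the direct
#' selection on each trait controlling for the others.
#'
#' @param w Relative fitness.
#' @param Z Matrix of standardized traits (individuals x traits).
#' @return List with `beta`, `se`, `p` (named per trait), `adj_r_squared`
#'   and `n`.
#' @examples
#' set.seed(1)
#' Z <- standardize_traits(matrix(rnorm(300), 100, 3,
#'                                dimnames = list(NULL, c("a", "b", "c"))))
#' w <- 1 + 0.4 * Z[, 1] + rnorm(100, 0, 0.1)
#' selection_gradients(relative_fitness(w), Z)$beta
#' @export
selection_gradients <- function(w, Z) {
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  if (length(w) != nrow(Z)) .stopf("`w` and `Z` must be paired")
  ok <- complete.cases(w, Z)
  w <- w[ok]; Z <- Z[ok, , drop = FALSE]
  k <- ncol(Z)
  if (length(w) <= k + 1)
    .stopf("need n > %d individuals for %d traits", k + 1, k)
  if (qr(Z)$rank < k) {
    cm <- abs(cor(Z)); diag(cm) <- 0
    pairs <- which(cm > 0.999, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    lab <- if (nrow(pairs)) paste(colnames(Z)[pairs[, 1]],
                                  colnames(Z)[pairs[, 2]],
                                  sep = " ~ ", collapse = ", ")
      else "unidentified combination"
    .stopf("collinear traits in the gradient model: %s", lab)
  }
  fit <- lm(w ~ Z)
  sm <- summary(fit)
  ct <- sm$coefficients[-1, , drop = FALSE]
  list(beta = stats::setNames(ct[, 1], colnames(Z)),
       se = stats::setNames(ct[, 2], colnames(Z)),
       p = stats::setNames(ct[, 4], colnames(Z)),
       adj_r_squared = sm$adj.r.squared,
       n = length(w))
}

#' Site-wise Lande-Arnold selection analysis
#'
#' For each site (by default a transect x transplant-elevation combination):
#' keeps survivors with complete trait and fitness values, computes relative
#' fitness and within-site standardized traits, then the selection
#' differential of every trait and the joint selection-gradient regression.
#'
#' @param records Transplant records (one row per individual) containing the
#'   trait columns, the fitness column and the site columns.
#' @param traits Character vector of trait columns to analyse.
#' @param fitness Fitness column, default `"final_biomass"` (individuals
#'   with `NA`, i.e. non-survivors, are excluded).
#' @param site_cols Columns whose combination defines a site.
#' @return Data.frame of class `selection_result`, one row per site x trait:
#'   `site`, `n`, `trait`, `S`, `p_S`, `beta`, `se_beta`, `p_beta`,
#'   `adj_r_squared`.
#' @examples
#' rec <- simulate_transplant(sim_params(seed = 3))
#' head(lande_arnold(rec, c("height", "leaf_area", "sla")))
#' @export
lande_arnold <- function(records, traits, fitness = "final_biomass",
                         site_cols = c("transect", "elevation_transplant")) {
  miss <- setdiff(c(traits, fitness, site_cols), names(records))
  if (length(miss)) .stopf("missing column(s): %s", paste(miss, collapse = ", "))
  site <- interaction(records[site_cols], sep = ":", drop = TRUE)
  rows <- lapply(levels(site), function(s) {
    d <- records[site == s, c(traits, fitness), drop = FALSE]
    d <- d[complete.cases(d), , drop = FALSE]
    if (nrow(d) <= length(traits) + 1)
      .stopf("site %s: only %d usable individuals for %d traits",
             s, nrow(d), length(traits))
    w <- relative_fitness(d[[fitness]])
    Z <- tryCatch(standardize_traits(d[traits]),
                  error = function(e) .stopf("site %s: %s", s, conditionMessage(e)))
    grad <- selection_gradients(w, Z)
    per_trait <- lapply(traits, function(tr) {
      sd_ <- selection_differential(w, Z[, tr])
      data.frame(site = s, n = nrow(d), trait = tr,
                 S = sd_$S, p_S = sd_$p,
                 beta = grad$beta[[tr]], se_beta = grad$se[[tr]],
                 p_beta = grad$p[[tr]],
                 adj_r_squared = grad$adj_r_squared,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_trait)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("selection_result", "data.frame")
  out
}

#' @export
print.selection_result <- function(x, digits = 3, ...) {
  cat("Site-specific selection analysis (S = cov(w, z); beta from joint OLS)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-site population trait means
#'
#' Mean trait values of the experimental individuals at each site, on the
#' same raw scale as the trait columns; the local reference against which
#' the community-weighted mean is compared.
#'
#' @inheritParams lande_arnold
#' @return Long data.frame with `site`, `trait`, `mean`.
#' @export
population_trait_means <- function(records, traits,
                                   site_cols = c("transect",
                                                 "elevation_transplant")) {
  site <- interaction(records[site_cols], sep = ":", drop = TRUE)
  out <- do.call(rbind, lapply(levels(site), function(s) {
    d <- records[site == s, traits, drop = FALSE]
    data.frame(site = s, trait = traits,
               mean = vapply(traits, function(tr) mean(d[[tr]], na.rm = TRUE),
                             numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Does selection point toward the community-weighted mean?
#'
#' Scores each site x trait cell as consistent when the sign of the
#' selection differential matches the sign of (CWM - local population
#' mean), i.e. selection pushes the population toward the community
#' optimum. Exact sign ties (S = 0 or CWM equal to the population mean) are
#' scored indeterminate and excluded from the consistency fraction. The
#' selection differentials and the CWM/population means must be declared on
#' the same trait scale.
#'
#' @param selection A `selection_result` from [lande_arnold()].
#' @param cwm_table Data.frame `site`, `trait`, `cwm`.
#' @param pop_means Data.frame `site`, `trait`, `mean` (see
#'   [population_trait_means()]).
#' @param scale_selection,scale_cwm Declared trait scales (free-form labels,
#'   e.g. `"raw"` or `"transformed"`); a mismatch is an error.
#' @return Data.frame of class `optimality_check` with per-cell signs,
#'   `consistent` (logical, `NA` when indeterminate) and the overall
#'   consistency fraction as attribute `"consistency"`.
#' @export
cwm_optimality <- function(selection, cwm_table, pop_means,
                           scale_selection = "raw", scale_cwm = "raw") {
  if (!identical(scale_selection, scale_cwm))
    .stopf("trait scale mismatch: selection on '%s' but CWM on '%s'",
           scale_selection, scale_cwm)
  need <- function(df, cols, what) {
    if (!all(cols %in% names(df)))
      .stopf("`%s` needs columns %s", what, paste(cols, collapse = ", "))
  }
  need(selection, c("site", "trait", "S"), "selection")
  need(cwm_table, c("site", "trait", "cwm"), "cwm_table")
  need(pop_means, c("site", "trait", "mean"), "pop_means")

  out <- merge(merge(as.data.frame(selection)[c("site", "trait", "S")],
                     cwm_table[c("site", "trait", "cwm")],
                     by = c("site", "trait")),
               pop_means[c("site", "trait", "mean")],
               by = c("site", "trait"))
  if (!nrow(out)) .stopf("no overlapping site x trait cells")
  out$delta <- out$cwm - out$mean
  out$consistent <- ifelse(out$S == 0 | out$delta == 0, NA,
                           sign(out$S) == sign(out$delta))
  frac <- if (all(is.na(out$consistent))) NA_real_ else
    mean(out$consistent, na.rm = TRUE)
  attr(out, "consistency") <- frac
  class(out) <- c("optimality_check", "data.frame")
  out
}

#' @export
print.optimality_check <- function(x, digits = 3, ...) {
  cat("CWM-optimality check: sign(S) vs sign(CWM - population mean)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  cat("consistency fraction:",
      round(attr(x, "consistency"), 3),
      "(indeterminate cells excluded)\n")
  invisible(x)
}
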