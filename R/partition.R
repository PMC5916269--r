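# Partitioning plastic (E), genetic (G) and GxE sources of intraspecific
# variation from a reciprocal transplant.
#
# The workhorse model, fitted per transformed trait, is
#   trait ~ elevation_origin + elevation_transplant +
#           elevation_origin:elevation_transplant + transect +
#           block(within transect x transplant site) + init_biomass
# with sum-to-zero factor coding. Blocks enter as a fixed nested factor,
# coded as an explicit within-cell sum-to-zero contrast matrix, which keeps
# every marginal (type III) sum of squares well defined in unbalanced data.
# The plasticity share is %E = 100 * SS_E / (SS_E + SS_G), where SS_E is the
# marginal SS of the elevation of transplant and SS_G that of the elevation
# of origin; the GxE interaction cannot be assigned to either source and is
# excluded from the ratio.

#' Default trait transformation map
#'
#' Height is square-root transformed; leaf area and SLA are log transformed,
#' the usual variance-stabilizing choices for these traits.
#'
#' @return Named character vector trait -> transform.
#' @export
trait_transforms <- function() {
  c(height = "sqrt", leaf_area = "log", sla = "log")
}

#' Apply variance-stabilizing transforms to trait columns
#'
#' Adds a transformed column `<trait>_t` for every entry of the transform
#' map; original columns are untouched. Domain violations (negative values
#' under sqrt, non-positive under log) are an error naming the offending
#' records.
#'
#' @param records Transplant records (data.frame with the trait columns).
#' @param transforms Named character vector trait -> `"sqrt"`, `"log"` or
#'   `"identity"` (default [trait_transforms()] restricted to columns
#'   present).
#' @return `records` with the transformed columns appended.
#' @examples
#' d <- data.frame(individual_id = "a", height = 16)
#' apply_transform(d, c(height = "sqrt"))$height_t  # 4
#' @export
apply_transform <- function(records, transforms = NULL) {
  transforms <- transforms %||%
    trait_transforms()[intersect(names(trait_transforms()), names(records))]
  if (!length(transforms)) .stopf("no transformable trait columns found")
  if (is.null(names(transforms)))
    .stopf("`transforms` must be named by trait")
  ids <- records$individual_id %||% rownames(records)
  for (tr in names(transforms)) {
    if (!tr %in% names(records)) .stopf("trait column '%s' not found", tr)
    how <- transforms[[tr]]
    if (!how %in% c("sqrt", "log", "identity"))
      .stopf("unknown transform '%s' for trait '%s'", how, tr)
    x <- records[[tr]]
    bad <- if (how == "sqrt") which(x < 0) else
      if (how == "log") which(x <= 0) else integer(0)
    if (length(bad))
      .stopf("%s transform domain violation for trait '%s' in record(s): %s",
             how, tr, paste(ids[bad], collapse = ", "))
    records[[paste0(tr, "_t")]] <- .fwd_transform(x, how)
  }
  records
}

# Within-cell sum-to-zero block coding: for each (transect, transplant
# elevation) cell with b blocks, b-1 contrast columns that are zero outside
# the cell and sum to zero inside it. Orthogonal to every cell-level term.
.block_matrix <- function(transect, elevation_transplant, block) {
  cell <- interaction(transect, elevation_transplant, drop = TRUE)
  cols <- list()
  for (cl in levels(cell)) {
    in_cell <- cell == cl
    blk <- factor(block[in_cell])
    if (nlevels(blk) < 2) next
    cm <- contr.sum(nlevels(blk))
    rownames(cm) <- levels(blk)
    m <- matrix(0, length(block), ncol(cm))
    m[in_cell, ] <- cm[as.character(blk), , drop = FALSE]
    colnames(m) <- paste0(cl, ".b", seq_len(ncol(cm)))
    cols[[cl]] <- m
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

#' Fit the trait partition model
#'
#' Least-squares fit of a transformed trait (or other gaussian response) on
#' elevation of origin, elevation of transplant, their interaction, transect,
#' a fixed nested block term and the initial-biomass covariate, all under
#' sum-to-zero coding so that marginal (type III) sums of squares are
#' meaningful. Rows with missing response or covariate are dropped. When
#' only one transect (or one block per site) is present the corresponding
#' term is dropped with a warning rather than failing.
#'
#' @param records Transplant records; must contain `elevation_origin`,
#'   `elevation_transplant`, `transect`, `block` and the response column.
#' @param response Name of the (transformed) response column.
#' @param covariate Name of the covariate column, or `NULL` to omit.
#' @param include_interaction Include the origin x transplant term
#'   (default `TRUE`).
#' @return Object of class `trait_fit`: the underlying `lm` fit plus the
#'   model frame and term bookkeeping used by [type3_anova()] and
#'   [lsmeans_pairwise()].
#' @export
fit_trait_model <- function(records, response, covariate = "init_biomass",
                            include_interaction = TRUE) {
  mf <- .build_frame(records, response, covariate)
  mf$response <- response
  fam_terms <- .design_terms(mf, covariate, include_interaction)
  fit <- lm(fam_terms$formula, data = fam_terms$data,
            contrasts = fam_terms$contrasts)
  .check_aliasing(fit, fam_terms)
  structure(list(lm = fit, data = fam_terms$data, response = response,
                 covariate = mf$covariate, terms = fam_terms$labels,
                 family = "gaussian"),
            class = "trait_fit")
}

.build_frame <- function(records, response, covariate) {
  need <- c("elevation_origin", "elevation_transplant", "transect", "block",
            response)
  miss <- setdiff(need, names(records))
  if (length(miss)) .stopf("missing column(s): %s", paste(miss, collapse = ", "))
  d <- records
  keep <- !is.na(d[[response]])
  if (!is.null(covariate)) {
    if (!covariate %in% names(d)) .stopf("covariate column '%s' not found", covariate)
    keep <- keep & !is.na(d[[covariate]])
  }
  d <- d[keep, , drop = FALSE]
  if (!nrow(d)) .stopf("no complete rows for response '%s'", response)

  elev <- intersect(.elev_levels, unique(c(as.character(d$elevation_origin),
                                           as.character(d$elevation_transplant))))
  if (!length(elev)) elev <- sort(unique(as.character(d$elevation_transplant)))
  d$elevation_origin <- factor(as.character(d$elevation_origin), levels = elev)
  d$elevation_transplant <- factor(as.character(d$elevation_transplant),
                                   levels = elev)
  d$transect <- factor(as.character(d$transect))
  d <- droplevels(d)
  for (f in c("elevation_origin", "elevation_transplant")) {
    if (nlevels(d[[f]]) < 2)
      .stopf("factor '%s' has fewer than 2 levels in the data", f)
  }
  list(data = d, covariate = covariate)
}

.design_terms <- function(mf, covariate, include_interaction) {
  d <- mf$data
  labels <- c("elevation_origin", "elevation_transplant")
  if (include_interaction) {
    cells <- table(d$elevation_origin, d$elevation_transplant)
    if (any(cells == 0))
      .stopf("empty origin x transplant cell(s): %s",
             paste(apply(which(cells == 0, arr.ind = TRUE), 1, function(i)
               paste(rownames(cells)[i[1]], colnames(cells)[i[2]], sep = ":")),
               collapse = ", "))
    labels <- c(labels, "elevation_origin:elevation_transplant")
  }
  use_transect <- nlevels(d$transect) >= 2
  if (!use_transect)
    .warnf("only one transect present; dropping the transect term")
  if (use_transect) labels <- c(labels, "transect")

  blk <- .block_matrix(d$transect, d$elevation_transplant, d$block)
  if (is.null(blk)) {
    .warnf("no within-site block replication; dropping the block term")
  } else {
    mf$data$`.blk` <- blk
    labels <- c(labels, ".blk")
  }
  if (!is.null(mf$covariate)) labels <- c(labels, mf$covariate)

  fml <- stats::reformulate(
    c("elevation_origin * elevation_transplant"[include_interaction],
      if (!include_interaction) c("elevation_origin", "elevation_transplant"),
      "transect"[use_transect], ".blk"[!is.null(blk)],
      if (!is.null(mf$covariate)) mf$covariate),
    response = mf$response %||% NULL)
  contr <- list(elevation_origin = "contr.sum",
                elevation_transplant = "contr.sum")
  if (use_transect) contr$transect <- "contr.sum"
  list(formula = fml, contrasts = contr, labels = labels, data = mf$data)
}

.check_aliasing <- function(fit, fam_terms) {
  cf <- coef(fit)
  if (!anyNA(cf)) return(invisible())
  asgn <- fit$assign
  labs <- c("(Intercept)", attr(terms(fit), "term.labels"))
  bad <- unique(labs[asgn[is.na(cf)] + 1])
  bad <- setdiff(bad, ".blk")  # block contrasts may legitimately collapse
  if (length(bad))
    .stopf("rank-deficient design: aliased term(s) %s",
           paste(bad, collapse = ", "))
  invisible()
}

#' @export
print.trait_fit <- function(x, ...) {
  cat("Transplant partition model (", x$family, ") for '", x$response,
      "'\n", sep = "")
  cat("  n =", nrow(x$data), " terms:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Type III (marginal) ANOVA table
#'
#' For every model term, the marginal sum of squares is the increase in
#' residual SS when that term's columns alone are removed from the full
#' model matrix, with all other terms retained -- the type III test under
#' sum-to-zero coding. F statistics use the full-model residual mean square.
#' For binomial fits (from [fit_survival_model()]) the analogous per-term
#' likelihood-ratio deviances and chi-square tests are returned.
#'
#' @param fit A `trait_fit` from [fit_trait_model()] or
#'   [fit_survival_model()].
#' @return A data.frame of class `anova_table` with columns `term`, `df`,
#'   `ss` (deviance for binomial), `ms`, `statistic` (F or Chisq) and
#'   `p_value`, plus a residual row for gaussian fits. Terms whose marginal
#'   test is non-estimable (0 df after aliasing) get `NA` statistics.
#' @examples
#' rec <- apply_transform(simulate_transplant(sim_params(seed = 7)))
#' fit <- fit_trait_model(rec, "height_t")
#' type3_anova(fit)
#' @export
type3_anova <- function(fit) {
  if (!inherits(fit, "trait_fit")) .stopf("`fit` must come from fit_trait_model()")
  if (fit$family == "binomial") return(.type3_deviance(fit))
  X <- model.matrix(fit$lm)
  asgn <- attr(X, "assign")
  y <- model.response(model.frame(fit$lm))
  qr_full <- qr(X)
  rss_full <- sum(qr.resid(qr_full, y)^2)
  rank_full <- qr_full$rank
  n <- length(y)
  df_res <- n - rank_full
  ms_res <- rss_full / df_res

  labs <- attr(terms(fit$lm), "term.labels")
  rows <- lapply(seq_along(labs), function(ti) {
    keep <- asgn != ti
    qr_red <- qr(X[, keep, drop = FALSE])
    df <- rank_full - qr_red$rank
    ss <- sum(qr.resid(qr_red, y)^2) - rss_full
    if (df == 0)
      return(data.frame(term = labs[ti], df = 0L, ss = NA_real_,
                        ms = NA_real_, statistic = NA_real_,
                        p_value = NA_real_))
    ss <- max(ss, 0)
    f <- (ss / df) / ms_res
    data.frame(term = labs[ti], df = as.integer(df), ss = ss, ms = ss / df,
               statistic = f, p_value = pf(f, df, df_res, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(term = "Residuals", df = as.integer(df_res),
                               ss = rss_full, ms = ms_res,
                               statistic = NA_real_, p_value = NA_real_))
  rownames(out) <- NULL
  attr(out, "family") <- "gaussian"
  attr(out, "response") <- fit$response
  class(out) <- c("anova_table", "data.frame")
  out
}

.type3_deviance <- function(fit) {
  X <- model.matrix(fit$lm)
  asgn <- attr(X, "assign")
  y <- fit$lm$y
  dev_full <- fit$lm$deviance
  rank_full <- qr(X)$rank
  labs <- attr(terms(fit$lm), "term.labels")
  rows <- lapply(seq_along(labs), function(ti) {
    keep <- asgn != ti
    red <- suppressWarnings(
      stats::glm.fit(X[, keep, drop = FALSE], y, family = binomial(),
                     control = stats::glm.control(maxit = 100)))
    df <- rank_full - red$rank
    dev <- red$deviance - dev_full
    if (df == 0)
      return(data.frame(term = labs[ti], df = 0L, ss = NA_real_,
                        ms = NA_real_, statistic = NA_real_,
                        p_value = NA_real_))
    dev <- max(dev, 0)
    data.frame(term = labs[ti], df = as.integer(df), ss = dev, ms = dev / df,
               statistic = dev,
               p_value = pchisq(dev, df, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "family") <- "binomial"
  attr(out, "response") <- fit$response
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, digits = 4, ...) {
  fam <- attr(x, "family")
  cat("Type III ", if (fam == "binomial") "analysis of deviance"
      else "ANOVA", " for '", attr(x, "response"), "'\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plasticity share of elevation-explained variation
#'
#' `%E = 100 * SS_E / (SS_E + SS_G)`: the share of the elevation signal in a
#' trait attributable to the growing environment (elevation of transplant,
#' plasticity) as opposed to the elevation of origin (genetic
#' differentiation). The GxE interaction cannot be assigned to either source
#' and never enters the ratio. The ratio is undefined (NA) when both sums of
#' squares are zero; it is invariant to rescaling the response.
#'
#' @param ss_e Marginal SS explained by elevation of transplant.
#' @param ss_g Marginal SS explained by elevation of origin.
#' @return Percentage in `[0, 100]`, or `NA` when undefined.
#' @examples
#' plasticity_share(3, 1)                      # 75
#' plasticity_share(2 * 10.26, 2 * 4.75)       # ~68.4, height-like
#' @export
plasticity_share <- function(ss_e, ss_g) {
  if (length(ss_e) != 1 || length(ss_g) != 1 || !is.finite(ss_e) ||
      !is.finite(ss_g) || ss_e < 0 || ss_g < 0)
    .stopf("`ss_e` and `ss_g` must be single non-negative numbers")
  if (ss_e + ss_g == 0) return(NA_real_)
  100 * ss_e / (ss_e + ss_g)
}

#' Partition a trait's elevation signal into plastic and genetic shares
#'
#' Extracts the marginal SS of elevation of transplant (E), elevation of
#' origin (G) and their interaction from a type III table and applies the
#' plasticity-share ratio. Works on gaussian SS and, as a documented
#' deviance-scale analogue, on binomial analysis-of-deviance tables.
#'
#' @param anova An `anova_table` from [type3_anova()].
#' @param trait Optional trait label for the output row (defaults to the
#'   table's response).
#' @return Data.frame of class `partition_result` with `trait`, `ss_e`,
#'   `ss_g`, `ss_gxe`, `percent_e`, `percent_g`.
#' @export
percent_plasticity <- function(anova, trait = NULL) {
  if (!inherits(anova, "anova_table")) .stopf("`anova` must be an anova_table")
  pick <- function(term) {
    i <- match(term, anova$term)
    if (is.na(i)) NA_real_ else anova$ss[i]
  }
  ss_e <- pick("elevation_transplant")
  ss_g <- pick("elevation_origin")
  if (is.na(ss_e) || is.na(ss_g))
    .stopf("table lacks elevation_transplant / elevation_origin rows")
  ss_gxe <- pick("elevation_origin:elevation_transplant")
  pe <- plasticity_share(ss_e, ss_g)
  out <- data.frame(trait = trait %||% attr(anova, "response") %||% NA_character_,
                    ss_e = ss_e, ss_g = ss_g, ss_gxe = ss_gxe,
                    percent_e = pe,
                    percent_g = if (is.na(pe)) NA_real_ else 100 - pe,
                    stringsAsFactors = FALSE)
  class(out) <- c("partition_result", "data.frame")
  out
}

#' @export
print.partition_result <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], signif, digits)
  cat("Plastic vs genetic partition of the elevation signal\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fit the survival model
#'
#' Logit-link binomial fit of summer survival on the same design as
#' [fit_trait_model()]. Complete separation is flagged: any origin x
#' transplant x transect cell where all plants share the same outcome is
#' named in a warning, and fits whose coefficients diverge are reported.
#'
#' @inheritParams fit_trait_model
#' @param response Binary response column (logical or 0/1), default
#'   `"survived"`.
#' @return A `trait_fit` with `family = "binomial"`; pass to [type3_anova()]
#'   for the per-term likelihood-ratio table.
#' @export
fit_survival_model <- function(records, response = "survived",
                               covariate = "init_biomass",
                               include_interaction = TRUE) {
  mf <- .build_frame(records, response, covariate)
  y <- mf$data[[response]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) .stopf("response '%s' must be binary", response)
  if (length(unique(y)) < 2)
    .stopf("all individuals share the same outcome; survival model is vacuous")
  mf$data[[response]] <- y

  cell <- interaction(mf$data$transect, mf$data$elevation_origin,
                      mf$data$elevation_transplant, drop = TRUE)
  prop <- tapply(y, cell, mean)
  sep <- names(prop)[prop %in% c(0, 1)]
  if (length(sep))
    .warnf("all-same survival outcome in cell(s) %s; separation possible",
           paste(sep, collapse = ", "))

  mf$response <- response
  fam_terms <- .design_terms(mf, covariate, include_interaction)
  fit <- suppressWarnings(glm(fam_terms$formula, data = fam_terms$data,
                              family = binomial(),
                              contrasts = fam_terms$contrasts, y = TRUE))
  if (any(abs(coef(fit)[!is.na(coef(fit))]) > 15))
    .warnf("very large coefficients: likely complete separation")
  structure(list(lm = fit, data = fam_terms$data, response = response,
                 covariate = mf$covariate, terms = fam_terms$labels,
                 family = "binomial"),
            class = "trait_fit")
}

#' Least-squares (estimated marginal) means and pairwise contrasts
#'
#' Model-adjusted cell means at each combination of the requested factors,
#' with the covariate held at its grand mean, block deviations at their
#' column means and remaining factors averaged with equal weights, plus all
#' pairwise contrasts with a multiplicity adjustment (Tukey by default).
#'
#' @param fit A `trait_fit`.
#' @param factors Character vector of factors defining the cells, default
#'   `c("elevation_origin", "elevation_transplant")`.
#' @param adjust Multiplicity adjustment passed to `emmeans::pairs()`.
#' @param by Optional conditioning factor: contrasts are computed within
#'   each of its levels (e.g. origins compared within each transplant site).
#' @return List of class `lsmeans_result` with data.frames `means` and
#'   `contrasts` (on the model/link scale).
#' @export
lsmeans_pairwise <- function(fit, factors = c("elevation_origin",
                                              "elevation_transplant"),
                             adjust = "tukey", by = NULL) {
  if (!inherits(fit, "trait_fit")) .stopf("`fit` must come from fit_trait_model()")
  missing_f <- setdiff(c(factors, by), fit$terms)
  if (length(missing_f))
    .stopf("factor(s) not in the model: %s", paste(missing_f, collapse = ", "))
  spec <- stats::reformulate(factors)
  em <- emmeans::emmeans(fit$lm, spec, by = by, data = fit$data)
  means <- as.data.frame(em)
  ctr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = adjust))
  structure(list(means = means, contrasts = ctr, adjust = adjust),
            class = "lsmeans_result")
}

#' @export
print.lsmeans_result <- function(x, digits = 4, ...) {
  cat("Least-squares means (model scale)\n")
  m <- x$means; m[] <- lapply(m, function(c) if (is.numeric(c)) signif(c, digits) else c)
  print(m, row.names = FALSE)
  cat("\nPairwise contrasts (", x$adjust, " adjusted)\n", sep = "")
  ct <- x$contrasts; ct[] <- lapply(ct, function(c) if (is.numeric(c)) signif(c, digits) else c)
  print(ct, row.names = FALSE)
  invisible(x)
}

#' Stepwise initial-biomass predictor
#'
#' Selects a linear model for final dry biomass from a set of candidate
#' morphological predictors by bidirectional stepwise search on AIC,
#' starting from the intercept-only model. The fitted values serve as the
#' initial-biomass covariate for individuals measured before transplanting.
#'
#' @param data Data.frame holding the response and candidate columns.
#' @param response Response column name (default `"final_biomass"`).
#' @param candidates Character vector of candidate predictor columns.
#' @param criterion `"AIC"` (default) or `"BIC"`; AIC admits a spurious
#'   predictor with probability about 0.16, BIC is stricter in moderate
#'   samples.
#' @param trace Show the selection path (default `FALSE`); the path is
#'   always recorded in the result.
#' @return List of class `init_biomass_fit`: `model` (the selected `lm`),
#'   `selected` (chosen predictors), `r_squared`, `path` (selection log) and
#'   `predictions` for all rows with complete candidates.
#' @export
fit_initial_biomass <- function(data, response = "final_biomass",
                                candidates, criterion = c("AIC", "BIC"),
                                trace = FALSE) {
  criterion <- match.arg(criterion)
  miss <- setdiff(c(response, candidates), names(data))
  if (length(miss)) .stopf("missing column(s): %s", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[c(response, candidates)]), , drop = FALSE]
  if (nrow(d) <= length(candidates) + 2)
    .stopf("need more than %d complete rows for %d candidates",
           length(candidates) + 2, length(candidates))

  cx <- as.matrix(d[candidates])
  if (length(candidates) > 1) {
    r <- qr(scale(cx, scale = FALSE))
    if (r$rank < ncol(cx)) {
      dropped <- candidates[-sort(r$pivot[seq_len(r$rank)])]
      .warnf("collinear candidate(s): %s", paste(dropped, collapse = ", "))
    }
  }

  null_fit <- lm(stats::reformulate("1", response), data = d)
  scope <- stats::reformulate(candidates)
  k <- if (criterion == "BIC") log(nrow(d)) else 2
  path <- capture.output(
    sel <- step(null_fit, scope = list(lower = ~1, upper = scope),
                direction = "both", trace = 1, k = k)
  )
  if (trace) cat(path, sep = "\n")
  selected <- attr(terms(sel), "term.labels")
  preds <- predict(sel, newdata = data)
  structure(list(model = sel, selected = selected,
                 r_squared = summary(sel)$r.squared,
                 adj_r_squared = summary(sel)$adj.r.squared,
                 path = path, predictions = preds),
            class = "init_biomass_fit")
}

#' @export
print.init_biomass_fit <- function(x, ...) {
  cat("Stepwise initial-biomass model (AIC, bidirectional)\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(intercept only)", "\n")
  cat("  R^2 =", round(x$r_squared, 3),
      " adj R^2 =", round(x$adj_r_squared, 3), "\n")
  invisible(x)
}
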