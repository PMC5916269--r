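# Community-weighted-mean trait turnover and its decomposition into
# species-turnover (SPT), intraspecific (ITV) and covariation components.
#
# Two CWM series are compared along a gradient: the "specific" CWM built
# from site-local trait values (which carries ITV) and the "fixed" CWM
# built from gradient-wide species means (species turnover only). Their
# difference is the intraspecific series, and sums of squares of the three
# series obey the exact identity
#   SS_specific = SS_fixed + SS_intra + SS_cov
# both for the gradient-explained and the total variation, with the
# covariation term defined as the remainder (it may be negative).

#' Community dataset container
#'
#' Holds site information, site-by-species relative abundances and one or
#' more site-by-species matrices of site-specific trait values.
#'
#' @param sites data.frame with columns `site` (unique ids) and `gradient`
#'   (numeric position, e.g. elevation in metres); extra columns (such as a
#'   transect label) are kept.
#' @param abundance Numeric sites x species matrix of non-negative
#'   abundances; rows are renormalized to sum to 1, with a warning when a
#'   row sum is off by more than `1e-6`.
#' @param traits Named list of sites x species matrices of site-specific
#'   trait values (`NA` allowed where a species is absent).
#' @return An object of class `community_dataset`.
#' @export
community_dataset <- function(sites, abundance, traits) {
  sites <- as.data.frame(sites)
  if (!all(c("site", "gradient") %in% names(sites)))
    .stopf("`sites` needs columns 'site' and 'gradient'")
  if (anyDuplicated(sites$site)) .stopf("duplicate site ids")
  abundance <- as.matrix(abundance)
  if (nrow(abundance) != nrow(sites))
    .stopf("abundance matrix must have one row per site")
  if (any(abundance < 0, na.rm = TRUE)) .stopf("negative abundances")
  if (anyNA(abundance)) .stopf("missing abundances are not allowed")
  rs <- rowSums(abundance)
  if (any(rs == 0))
    .stopf("all-zero abundance row at site(s) %s: cannot renormalize",
           paste(sites$site[rs == 0], collapse = ", "))
  if (any(abs(rs - 1) > 1e-6))
    .warnf("abundances at %d site(s) do not sum to 1; renormalizing",
           sum(abs(rs - 1) > 1e-6))
  abundance <- sweep(abundance, 1, rs, "/")
  if (is.null(colnames(abundance)))
    colnames(abundance) <- sprintf("sp%02d", seq_len(ncol(abundance)))
  rownames(abundance) <- sites$site

  if (!is.list(traits) || is.null(names(traits)) || !all(nzchar(names(traits))))
    .stopf("`traits` must be a named list of trait matrices")
  traits <- lapply(traits, function(x) {
    x <- as.matrix(x)
    if (!identical(dim(x), dim(abundance)))
      .stopf("each trait matrix must match the abundance matrix shape")
    dimnames(x) <- dimnames(abundance)
    x
  })

  structure(list(sites = sites, abundance = abundance, traits = traits),
            class = "community_dataset")
}

#' @export
print.community_dataset <- function(x, ...) {
  cat("Community dataset:", nrow(x$abundance), "sites x",
      ncol(x$abundance), "species;",
      length(x$traits), "trait(s):",
      paste(names(x$traits), collapse = ", "), "\n")
  cat("Gradient range:", paste(signif(range(x$sites$gradient), 5),
                               collapse = " - "), "\n")
  invisible(x)
}

#' Gradient-wide species mean traits
#'
#' The "fixed" trait value of each species: its mean across sites, by
#' default weighted by its relative abundance at each site (unweighted
#' available as an option).
#'
#' @param dataset A [community_dataset()].
#' @param trait Trait name (defaults to the first trait).
#' @param weighted Abundance-weighted (default) or plain mean across sites
#'   where the species has a trait value.
#' @return Named per-species vector of gradient-wide means.
#' @export
species_mean_traits <- function(dataset, trait = names(dataset$traits)[1],
                                weighted = TRUE) {
  x <- .get_trait(dataset, trait)
  p <- dataset$abundance
  vapply(seq_len(ncol(x)), function(i) {
    ok <- !is.na(x[, i])
    if (!any(ok)) return(NA_real_)
    w <- if (weighted) p[ok, i] else rep(1, sum(ok))
    if (sum(w) == 0) mean(x[ok, i]) else sum(w * x[ok, i]) / sum(w)
  }, numeric(1)) |> stats::setNames(colnames(x))
}

.get_trait <- function(dataset, trait) {
  if (!inherits(dataset, "community_dataset"))
    .stopf("`dataset` must be a community_dataset")
  if (!trait %in% names(dataset$traits))
    .stopf("unknown trait '%s'", trait)
  dataset$traits[[trait]]
}

#' Community-weighted mean traits
#'
#' CWM_j = sum_i p_ij x_ij with site-local trait values (`mode =
#' "specific"`, includes intraspecific variation) or CWM_j = sum_i p_ij
#' xbar_i with gradient-wide species means (`mode = "fixed"`, species
#' turnover only).
#'
#' @param dataset A [community_dataset()].
#' @param trait Trait name.
#' @param mode `"specific"` or `"fixed"`.
#' @param fixed_means Optional per-species means to use in fixed mode
#'   (default [species_mean_traits()]).
#' @param missing How to treat a species with positive abundance but no
#'   site-specific trait value in specific mode: `"strict"` (error, naming
#'   site and species) or `"substitute"` (use the gradient-wide mean, with a
#'   warning).
#' @return Named per-site vector of community-weighted means.
#' @examples
#' cd <- simulate_community(n_sites = 5, species_pool = 3, seed = 1)
#' compute_cwm(cd, mode = "specific")
#' @export
compute_cwm <- function(dataset, trait = names(dataset$traits)[1],
                        mode = c("specific", "fixed"),
                        fixed_means = NULL,
                        missing = c("strict", "substitute")) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  x <- .get_trait(dataset, trait)
  p <- dataset$abundance
  xbar <- fixed_means %||% species_mean_traits(dataset, trait)

  if (mode == "fixed") {
    if (anyNA(xbar[colSums(p > 0) > 0]))
      .stopf("species present somewhere lack a gradient-wide mean")
    return(stats::setNames(drop(p %*% xbar), rownames(p)))
  }

  bad <- which(p > 0 & is.na(x), arr.ind = TRUE)
  if (nrow(bad)) {
    labs <- paste0(rownames(p)[bad[, 1]], "/", colnames(p)[bad[, 2]])
    if (missing == "strict")
      .stopf("missing site-specific trait value with positive abundance: %s",
             paste(labs, collapse = ", "))
    .warnf("substituting gradient-wide means for %d missing site/species value(s)",
           nrow(bad))
    x[cbind(bad[, 1], bad[, 2])] <- xbar[bad[, 2]]
  }
  x[is.na(x)] <- 0  # absent species contribute nothing
  stats::setNames(rowSums(p * x), rownames(p))
}

# explained and total sum of squares of y against the gradient model
.gradient_ss <- function(y, gradient, model) {
  tot <- sum((y - mean(y))^2)
  fit <- if (model == "factor") {
    lm(y ~ g, data = data.frame(y = y, g = factor(gradient)))
  } else {
    lm(y ~ g, data = data.frame(y = y, g = as.numeric(gradient)))
  }
  rss <- sum(stats::resid(fit)^2)
  c(explained = tot - rss, total = tot)
}

#' Decompose CWM trait turnover into turnover, ITV and covariation
#'
#' Computes the specific, fixed and intraspecific (specific - fixed) CWM
#' series, regresses each on the gradient, and reports explained and total
#' sums of squares for the species-turnover (fixed), intraspecific and
#' covariation components, together with the relative ITV share
#' `100 * SS_intra / (SS_intra + SS_fixed)` computed on the
#' gradient-explained components (total-variance shares are reported too).
#'
#' @param dataset A [community_dataset()].
#' @param traits Trait names (default all).
#' @param model Gradient model for the explained SS: `"linear"` regression
#'   on the numeric gradient (default) or `"factor"` one-way ANOVA on the
#'   gradient treated as categorical.
#' @param fixed_means,missing Passed to [compute_cwm()].
#' @return A data.frame of class `cwm_decomposition`, one row per trait,
#'   with columns `ss_specific`, `ss_fixed`, `ss_intra`, `ss_cov` (and their
#'   `*_total` counterparts), `itv_share`, `spt_share`,
#'   `itv_share_total`, `spt_share_total`. Shares are `NA` when the
#'   denominator is zero. The per-site CWM series are attached as attribute
#'   `"cwm"`.
#' @examples
#' cd <- simulate_community(n_sites = 8, species_pool = 4,
#'                          itv_slopes = 0.02, noise_sd = 0, seed = 2)
#' cwm_decompose(cd)
#' @export
cwm_decompose <- function(dataset, traits = names(dataset$traits),
                          model = c("linear", "factor"),
                          fixed_means = NULL,
                          missing = c("strict", "substitute")) {
  model <- match.arg(model)
  missing <- match.arg(missing)
  if (nrow(dataset$sites) < 2)
    .stopf("at least 2 sites are required to regress on the gradient")
  g <- dataset$sites$gradient

  series <- list()
  rows <- lapply(traits, function(tr) {
    cwm_s <- compute_cwm(dataset, tr, "specific", fixed_means, missing)
    cwm_f <- compute_cwm(dataset, tr, "fixed", fixed_means)
    cwm_i <- cwm_s - cwm_f
    series[[tr]] <<- data.frame(site = dataset$sites$site, gradient = g,
                                specific = cwm_s, fixed = cwm_f,
                                intra = cwm_i, row.names = NULL)
    s <- .gradient_ss(cwm_s, g, model)
    f <- .gradient_ss(cwm_f, g, model)
    i <- .gradient_ss(cwm_i, g, model)
    covar <- s - f - i  # remainder term, exact by construction

    share <- function(num, den) if (num + den <= 0) NA_real_ else
      100 * num / (num + den)
    data.frame(
      trait = tr,
      ss_specific = s[["explained"]], ss_fixed = f[["explained"]],
      ss_intra = i[["explained"]], ss_cov = covar[["explained"]],
      ss_specific_total = s[["total"]], ss_fixed_total = f[["total"]],
      ss_intra_total = i[["total"]], ss_cov_total = covar[["total"]],
      itv_share = share(i[["explained"]], f[["explained"]]),
      itv_share_total = share(i[["total"]], f[["total"]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$spt_share <- ifelse(is.na(out$itv_share), NA_real_, 100 - out$itv_share)
  out$spt_share_total <- ifelse(is.na(out$itv_share_total), NA_real_,
                                100 - out$itv_share_total)
  rownames(out) <- NULL
  attr(out, "cwm") <- series
  attr(out, "model") <- model
  class(out) <- c("cwm_decomposition", "data.frame")
  out
}

#' @export
print.cwm_decomposition <- function(x, digits = 4, ...) {
  cat("CWM turnover decomposition (", attr(x, "model"),
      " gradient model)\n", sep = "")
  df <- as.data.frame(x)
  print(cbind(df["trait"],
              round(df[c("ss_fixed", "ss_intra", "ss_cov", "ss_specific",
                         "itv_share", "spt_share")], digits)),
        row.names = FALSE)
  cat("shares are computed on gradient-explained SS;",
      "ss_cov is the covariation remainder\n")
  invisible(x)
}
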