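# File schemas, configuration and the end-to-end report.
#
# CSV is the single interchange format. Transplant records travel as one
# wide table (one row per individual); community data as a long
# site/species table plus a site table with gradient positions. A YAML (or
# list) configuration drives run_pipeline(), which executes
# simulate -> partition -> cwm -> selection -> optimality and writes tidy
# CSV outputs plus a plain-text summary with provenance (config hash,
# seed, package version) sufficient to reproduce every number.

.transplant_cols <- c("individual_id", "transect", "elevation_origin",
                      "elevation_transplant", "block", "init_biomass",
                      "survived", "final_biomass")

#' Read transplant records from CSV
#'
#' Validates the canonical schema: required columns `individual_id`,
#' `transect`, `elevation_origin`, `elevation_transplant`, `block`,
#' `init_biomass`, `survived`, `final_biomass`, plus at least one trait
#' column. Elevation labels must be low/mid/high; duplicate ids are an
#' error; missing values are preserved as `NA`.
#'
#' @param path CSV file path.
#' @return Data.frame of transplant records.
#' @export
read_transplant_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.transplant_cols, names(d))
  if (length(miss))
    .stopf("transplant file '%s' is missing required column(s): %s",
           path, paste(miss, collapse = ", "))
  if (anyDuplicated(d$individual_id))
    .stopf("duplicate individual_id: %s",
           paste(unique(d$individual_id[duplicated(d$individual_id)]),
                 collapse = ", "))
  for (col in c("elevation_origin", "elevation_transplant")) {
    bad <- setdiff(unique(d[[col]]), .elev_levels)
    if (length(bad))
      .stopf("unknown elevation label(s) in %s: %s", col,
             paste(bad, collapse = ", "))
    d[[col]] <- factor(d[[col]], levels = .elev_levels)
  }
  d$transect <- factor(d$transect)
  if (is.character(d$survived))
    d$survived <- toupper(d$survived) %in% c("TRUE", "T", "1", "YES")
  d$survived <- as.logical(d$survived)
  if (any(!is.na(d$final_biomass) & !d$survived))
    .warnf("final_biomass present for non-survivors; check the records")
  d
}

#' Write transplant records to CSV
#'
#' @param records Transplant records data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transplant_csv <- function(records, path) {
  miss <- setdiff(.transplant_cols, names(records))
  if (length(miss))
    .stopf("records are missing required column(s): %s",
           paste(miss, collapse = ", "))
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read community data from CSV
#'
#' Assembles a [community_dataset()] from a long table (`site`, `species`,
#' `abundance`, one column per trait) and a site table (`site`, `gradient`,
#' optional extras). Abundances are renormalized per site; deviations
#' beyond `1e-6` draw a warning. Unknown sites and negative abundances are
#' errors.
#'
#' @param site_path CSV with the site table.
#' @param long_path CSV with the long site/species table.
#' @return A [community_dataset()].
#' @export
read_community_csv <- function(site_path, long_path) {
  sites <- read.csv(site_path, stringsAsFactors = FALSE)
  if (!all(c("site", "gradient") %in% names(sites)))
    .stopf("site file needs columns 'site' and 'gradient'")
  long <- read.csv(long_path, stringsAsFactors = FALSE)
  if (!all(c("site", "species", "abundance") %in% names(long)))
    .stopf("community file needs columns 'site', 'species', 'abundance'")
  unknown <- setdiff(unique(long$site), sites$site)
  if (length(unknown))
    .stopf("site(s) in community file absent from site table: %s",
           paste(unknown, collapse = ", "))
  if (any(long$abundance < 0, na.rm = TRUE)) .stopf("negative abundance")
  trait_cols <- setdiff(names(long), c("site", "species", "abundance"))
  if (!length(trait_cols)) .stopf("community file has no trait columns")

  species <- sort(unique(long$species))
  p <- matrix(0, nrow(sites), length(species),
              dimnames = list(sites$site, species))
  tr <- lapply(trait_cols, function(cc)
    matrix(NA_real_, nrow(sites), length(species),
           dimnames = list(sites$site, species)))
  names(tr) <- trait_cols
  idx <- cbind(match(long$site, sites$site), match(long$species, species))
  p[idx] <- long$abundance
  for (cc in trait_cols) tr[[cc]][idx] <- long[[cc]]
  community_dataset(sites, p, tr)
}

#' Write community data to CSV
#'
#' Inverse of [read_community_csv()]: emits the site table and the long
#' site/species table (rows only where a species has positive abundance or
#' a trait value).
#'
#' @param dataset A [community_dataset()].
#' @param site_path,long_path Output paths.
#' @return `c(site_path, long_path)`, invisibly.
#' @export
write_community_csv <- function(dataset, site_path, long_path) {
  if (!inherits(dataset, "community_dataset"))
    .stopf("`dataset` must be a community_dataset")
  write.csv(dataset$sites, site_path, row.names = FALSE)
  p <- dataset$abundance
  keep <- p > 0 | Reduce(`|`, lapply(dataset$traits, function(x) !is.na(x)))
  idx <- which(keep, arr.ind = TRUE)
  long <- data.frame(site = rownames(p)[idx[, 1]],
                     species = colnames(p)[idx[, 2]],
                     abundance = p[idx], stringsAsFactors = FALSE)
  for (tr in names(dataset$traits)) long[[tr]] <- dataset$traits[[tr]][idx]
  long <- long[order(long$site, long$species), ]
  write.csv(long, long_path, row.names = FALSE, na = "")
  invisible(c(site_path, long_path))
}

#' Assemble and validate a pipeline configuration
#'
#' Accepts a YAML file path or a list. A configuration names, for each data
#' kind, either an input file or a simulate block (never both): `transplant`
#' with `file` or `simulate` (arguments to [sim_params()]), and optionally
#' `community` with `site_file` + `long_file` or `simulate` (arguments to
#' [simulate_community()]). Engine options: `transforms` (trait -> sqrt/
#' log/identity), `lsmeans_adjust`, `cwm_model` (linear/factor),
#' `selection_traits`, `stages`. A `seed` is required whenever any
#' simulation is requested.
#'
#' @param x Path to a YAML config or a list.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1) yaml::read_yaml(x)
  else if (is.list(x)) x
  else .stopf("`x` must be a YAML path or a list")

  tp <- cfg$transplant
  if (is.null(tp) || (is.null(tp$file) == is.null(tp$simulate)))
    .stopf("config needs `transplant` with exactly one of `file` or `simulate`")
  cm <- cfg$community
  if (!is.null(cm) &&
      (is.null(cm$simulate) == (is.null(cm$site_file) || is.null(cm$long_file))))
    .stopf("`community` needs exactly one of {site_file+long_file} or `simulate`")

  cfg$stages <- cfg$stages %||%
    c("partition", "selection", if (!is.null(cm)) c("cwm", "optimality"))
  bad <- setdiff(cfg$stages, c("partition", "survival", "cwm", "selection",
                               "optimality"))
  if (length(bad)) .stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (any(c("cwm", "optimality") %in% cfg$stages) && is.null(cm))
    .stopf("stage 'cwm'/'optimality' requested but no community data configured")
  if ("optimality" %in% cfg$stages &&
      !all(c("cwm", "selection") %in% c(cfg$stages)))
    .stopf("stage 'optimality' needs both 'cwm' and 'selection'")

  needs_sim <- !is.null(tp$simulate) || (!is.null(cm) && !is.null(cm$simulate))
  if (needs_sim && is.null(cfg$seed))
    .stopf("`seed` is required when simulation is requested")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$lsmeans_adjust <- cfg$lsmeans_adjust %||% "tukey"
  cfg$cwm_model <- cfg$cwm_model %||% "linear"
  cfg$verbose <- isTRUE(cfg$verbose)
  class(cfg) <- "run_config"
  cfg
}

.log <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages -- simulate or read the transplant data,
#' transform traits, fit the partition model and type III table per trait,
#' the survival model, the site-wise selection analysis, the CWM turnover
#' decomposition and the CWM-optimality check -- and writes every table as
#' tidy CSV into `out_dir` along with `summary.txt` carrying provenance
#' (config hash, seed, package version). Deterministic given the seed.
#'
#' @param config A [run_config()] (or list/path coercible to one).
#' @param out_dir Output directory, created if needed; `NULL` writes
#'   nothing.
#' @return List of class `report_bundle` with elements `partition`
#'   (per-trait ANOVA tables and the %E summary), `survival`, `selection`,
#'   `cwm`, `optimality`, `records`, and `provenance`.
#' @examples
#' cfg <- list(transplant = list(simulate = list()), seed = 11,
#'             stages = c("partition", "selection"))
#' bundle <- run_pipeline(cfg, out_dir = NULL)
#' bundle$partition$percent_e
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  prov <- list(config_hash = rlang::hash(unclass(cfg)), seed = cfg$seed,
               package_version = as.character(utils::packageVersion("traitmatch")),
               r_version = paste(R.version$major, R.version$minor, sep = "."))

  # --- data ------------------------------------------------------------
  if (!is.null(cfg$transplant$simulate)) {
    .log(cfg, "simulating transplant data (seed %d)", cfg$seed)
    sp <- do.call(sim_params, c(cfg$transplant$simulate,
                                list(seed = cfg$seed)))
    records <- simulate_transplant(sp)
    transforms <- sp$transforms
  } else {
    .log(cfg, "reading transplant data from %s", cfg$transplant$file)
    records <- read_transplant_csv(cfg$transplant$file)
    transforms <- unlist(cfg$transforms) %||%
      trait_transforms()[intersect(names(trait_transforms()), names(records))]
  }
  if (!is.null(cfg$transforms)) transforms <- unlist(cfg$transforms)
  traits <- names(transforms)
  records_t <- apply_transform(records, transforms)

  community <- NULL
  if (!is.null(cfg$community)) {
    community <- if (!is.null(cfg$community$simulate)) {
      do.call(simulate_community,
              c(cfg$community$simulate, list(seed = cfg$seed + 1L)))
    } else {
      read_community_csv(cfg$community$site_file, cfg$community$long_file)
    }
  }

  bundle <- list(records = records, provenance = prov)

  # --- partition -------------------------------------------------------
  if ("partition" %in% cfg$stages) {
    .log(cfg, "partitioning E/G/GxE for %d trait(s)", length(traits))
    tabs <- list(); pes <- list(); lsm <- list()
    for (tr in traits) {
      fit <- fit_trait_model(records_t, paste0(tr, "_t"))
      tabs[[tr]] <- type3_anova(fit)
      pes[[tr]] <- percent_plasticity(tabs[[tr]], trait = tr)
      lsm[[tr]] <- lsmeans_pairwise(fit, adjust = cfg$lsmeans_adjust)
    }
    bundle$partition <- list(anova = tabs,
                             percent_e = do.call(rbind, pes),
                             lsmeans = lsm)
    surv_fit <- tryCatch(fit_survival_model(records_t),
                         error = function(e) e)
    bundle$survival <- if (inherits(surv_fit, "error")) {
      .warnf("survival stage skipped: %s", conditionMessage(surv_fit))
      NULL
    } else list(anova = type3_anova(surv_fit))
  }

  # --- selection -------------------------------------------------------
  if ("selection" %in% cfg$stages) {
    sel_traits <- cfg$selection_traits %||% traits
    .log(cfg, "site-wise selection analysis")
    bundle$selection <- lande_arnold(records, sel_traits)
  }

  # --- community -------------------------------------------------------
  if ("cwm" %in% cfg$stages) {
    .log(cfg, "CWM turnover decomposition")
    bundle$cwm <- cwm_decompose(community, model = cfg$cwm_model)
  }

  if ("optimality" %in% cfg$stages) {
    cwm_tab <- cfg$optimality_cwm %||% NULL
    if (is.null(cwm_tab)) {
      # compare each analysed trait against the community trait CWM only
      # when site sets actually overlap; otherwise skip with a warning
      .warnf("no site-matched CWM table supplied; optimality check skipped")
    } else {
      bundle$optimality <- cwm_optimality(
        bundle$selection, cwm_tab,
        population_trait_means(records, unique(cwm_tab$trait)))
    }
  }

  class(bundle) <- "report_bundle"
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir, cfg)
  bundle
}

.write_bundle <- function(bundle, out_dir, cfg) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- bundle$provenance
  w <- function(df, name) write.csv(as.data.frame(df),
                                    file.path(out_dir, name),
                                    row.names = FALSE, na = "")
  lines <- c("traitmatch pipeline report",
             sprintf("config_hash: %s", prov$config_hash),
             sprintf("seed: %d", prov$seed),
             sprintf("package_version: %s", prov$package_version),
             sprintf("r_version: %s", prov$r_version), "")
  if (!is.null(bundle$partition)) {
    for (tr in names(bundle$partition$anova))
      w(bundle$partition$anova[[tr]], sprintf("anova_%s.csv", tr))
    w(bundle$partition$percent_e, "partition.csv")
    for (tr in names(bundle$partition$lsmeans)) {
      w(bundle$partition$lsmeans[[tr]]$means, sprintf("lsmeans_%s.csv", tr))
      w(bundle$partition$lsmeans[[tr]]$contrasts,
        sprintf("lsmeans_contrasts_%s.csv", tr))
    }
    pe <- bundle$partition$percent_e
    lines <- c(lines, "Plasticity share of the elevation signal (%E):",
               sprintf("  %-12s %6.1f%%", pe$trait, pe$percent_e), "")
  }
  if (!is.null(bundle$survival)) {
    w(bundle$survival$anova, "survival_anova.csv")
  }
  if (!is.null(bundle$selection)) {
    w(bundle$selection, "selection.csv")
    lines <- c(lines, sprintf("Selection analysis: %d site x trait rows",
                              nrow(bundle$selection)), "")
  }
  if (!is.null(bundle$cwm)) {
    w(bundle$cwm, "cwm_decomposition.csv")
    lines <- c(lines,
               "CWM turnover decomposition (ITV share, explained SS):",
               sprintf("  %-12s %6.1f%%", bundle$cwm$trait,
                       bundle$cwm$itv_share), "")
  }
  if (!is.null(bundle$optimality)) {
    w(bundle$optimality, "optimality.csv")
    lines <- c(lines, sprintf("CWM-optimality consistency: %.3f",
                              attr(bundle$optimality, "consistency")), "")
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("traitmatch report bundle\n")
  cat("  config:", x$provenance$config_hash, " seed:", x$provenance$seed, "\n")
  cat("  sections:",
      paste(intersect(c("partition", "survival", "selection", "cwm",
                        "optimality"), names(x)[!vapply(x, is.null, TRUE)]),
            collapse = ", "), "\n")
  invisible(x)
}
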