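## Case-study runner: from a delimited table of per-district legacy
## summaries (sample size, mean and variance of the log-transformed
## variable, proportion below a threshold) to complete sample-size
## tables for all approaches and criteria.

#' Read a legacy-summary table
#'
#' Reads a CSV with columns `district`, `n`, `mean_ln_zn`, `var_ln_zn`,
#' `prop_deficient`: one row per administrative unit, giving the number
#' of legacy observations, the sample mean and variance of the
#' log-transformed concentration, and the sample proportion below the
#' deficiency threshold.  A bundled example with the thirteen Andhra
#' Pradesh districts ships with the package.
#'
#' @param path Path to the CSV file.
#' @return A data frame with the validated columns.
#' @examples
#' tab <- read_legacy_summaries(
#'   system.file("extdata", "andhra_districts.csv", package = "ssdbayes"))
#' head(tab)
#' @export
read_legacy_summaries <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("district", "n", "mean_ln_zn", "var_ln_zn", "prop_deficient")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  validate_legacy_rows(tab)
  tab[need]
}

validate_legacy_rows <- function(tab) {
  bad <- character(0)
  if (any(!is.finite(tab$n) | tab$n <= 0)) bad <- c(bad, "n")
  if (any(!is.finite(tab$var_ln_zn) | tab$var_ln_zn <= 0)) {
    bad <- c(bad, "var_ln_zn")
  }
  if (any(!is.finite(tab$prop_deficient) | tab$prop_deficient < 0 |
            tab$prop_deficient > 1)) {
    bad <- c(bad, "prop_deficient")
  }
  if (any(!is.finite(tab$mean_ln_zn))) bad <- c(bad, "mean_ln_zn")
  if (length(bad)) {
    stop("invalid legacy summaries in fields: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

#' Derive district priors from a legacy summary
#'
#' Builds the two priors a district's legacy data imply: a
#' [normal_gamma_prior()] for the log-scale mean and precision (gamma
#' hyperparameters from the legacy variance and a chosen coefficient of
#' variation; flat prior on the mean, `n0 = 0`, for conservative sample
#' sizes) and a [beta_prior()] for the deficient areal fraction (mode at
#' the legacy proportion, prior sample size `round(n / n0_divisor)`).
#'
#' @param row A one-row data frame as returned by
#'   [read_legacy_summaries()] (or a list with the same fields).
#' @param cv_lambda Coefficient of variation of the gamma prior for the
#'   precision (default 0.25).
#' @param n0_divisor Legacy count divisor giving the beta prior sample
#'   size (default 1000).
#' @return A list with elements `mean` (normal-gamma prior) and `prop`
#'   (beta prior).
#' @examples
#' derive_district_priors(list(district = "Chittoor", n = 37978,
#'                             mean_ln_zn = -0.06, var_ln_zn = 0.41,
#'                             prop_deficient = 0.49))
#' @export
derive_district_priors <- function(row, cv_lambda = 0.25,
                                   n0_divisor = 1000) {
  validate_legacy_rows(as.data.frame(row[c("district", "n", "mean_ln_zn",
                                           "var_ln_zn",
                                           "prop_deficient")]))
  g <- gamma_from_mean_cv(row$var_ln_zn, cv_lambda)
  n0_beta <- max(0, floor(row$n / n0_divisor + 0.5))  # half rounds up
  list(mean = normal_gamma_prior(a = g$a, b = g$b, mu0 = row$mean_ln_zn,
                                 n0 = 0),
       prop = beta_from_mode_n0(row$prop_deficient, n0_beta))
}

#' Sample-size tables for a set of districts
#'
#' For every district in a legacy-summary table, computes the
#' frequentist sample size and the fully Bayesian and mixed
#' Bayesian-likelihood sizes under ALC, ACC and WOC — once for the
#' log-scale mean (interval length `mean_lmax`) and once for the
#' deficient areal fraction (length `prop_lmax`).
#'
#' @param summaries Data frame from [read_legacy_summaries()].
#' @param mean_lmax,prop_lmax Maximum interval lengths (defaults 0.2 and
#'   0.1).
#' @param coverage Interval coverage (default 0.95).
#' @param worst_level WOC assurance level (default 0.8).
#' @param cv_lambda,n0_divisor Passed to [derive_district_priors()].
#' @param verbose Print per-district progress to stderr.
#' @return A list of class `"ssd_tables"`: data frames `mean` and `prop`
#'   (columns `freq`, `alc`, `alc_mbl`, `acc`, `acc_mbl`, `woc`,
#'   `woc_mbl`, plus the surplus of legacy points over the largest
#'   required size), a data frame `achieved` with the attained criterion
#'   values, and the run `parameters`.
#' @examples
#' tab <- read_legacy_summaries(
#'   system.file("extdata", "andhra_districts.csv", package = "ssdbayes"))
#' ssd_tables(tab[tab$district == "Chittoor", ])
#' @export
ssd_tables <- function(summaries, mean_lmax = 0.2, prop_lmax = 0.1,
                       coverage = 0.95, worst_level = 0.8,
                       cv_lambda = 0.25, n0_divisor = 1000,
                       verbose = FALSE) {
  validate_legacy_rows(summaries)
  if (nrow(summaries) < 1) stop("no districts in input", call. = FALSE)
  cells <- expand.grid(approach = c("bayes", "mbl"),
                       criterion = c("alc", "acc", "woc"),
                       stringsAsFactors = FALSE)
  res_mean <- list()
  res_prop <- list()
  achieved <- list()
  for (i in seq_len(nrow(summaries))) {
    row <- summaries[i, ]
    if (verbose) message("district: ", row$district)
    pri <- derive_district_priors(row, cv_lambda, n0_divisor)
    rm_row <- list(district = row$district,
                   freq = n_mean_freq(sqrt(row$var_ln_zn), mean_lmax,
                                      coverage))
    rp_row <- list(district = row$district,
                   freq = n_prop_wald(row$prop_deficient, prop_lmax,
                                      coverage))
    for (j in seq_len(nrow(cells))) {
      cr <- cells$criterion[j]
      ap <- cells$approach[j]
      col <- if (ap == "mbl") paste0(cr, "_mbl") else cr
      sm <- ssd_mean(pri$mean,
                     precision_spec(mean_lmax, coverage, cr, ap,
                                    worst_level))
      sp <- ssd_prop(pri$prop,
                     precision_spec(prop_lmax, coverage, cr, ap,
                                    worst_level))
      rm_row[[col]] <- sm$n
      rp_row[[col]] <- sp$n
      achieved[[length(achieved) + 1L]] <-
        data.frame(district = row$district, target = "mean",
                   criterion = cr, approach = ap, n = sm$n,
                   achieved = sm$achieved)
      achieved[[length(achieved) + 1L]] <-
        data.frame(district = row$district, target = "prop",
                   criterion = cr, approach = ap, n = sp$n,
                   achieved = sp$achieved)
    }
    rm_row$surplus <- row$n - max(unlist(rm_row[-1]))
    rp_row$surplus <- row$n - max(unlist(rp_row[-1]))
    rm_row$backtransformed_lmax <-
      backtransform_length(mean_lmax, row$mean_ln_zn)
    res_mean[[i]] <- as.data.frame(rm_row)
    res_prop[[i]] <- as.data.frame(rp_row)
  }
  structure(list(
    mean = do.call(rbind, res_mean),
    prop = do.call(rbind, res_prop),
    achieved = do.call(rbind, achieved),
    parameters = list(mean_lmax = mean_lmax, prop_lmax = prop_lmax,
                      coverage = coverage, worst_level = worst_level,
                      cv_lambda = cv_lambda, n0_divisor = n0_divisor)),
    class = "ssd_tables")
}

#' @export
print.ssd_tables <- function(x, ...) {
  cat("Required sample sizes, log-scale mean (lmax =",
      x$parameters$mean_lmax, "):\n")
  print(x$mean, row.names = FALSE)
  cat("\nRequired sample sizes, deficient areal fraction (lmax =",
      x$parameters$prop_lmax, "):\n")
  print(x$prop, row.names = FALSE)
  invisible(x)
}

#' Write sample-size tables and a run manifest
#'
#' Writes the two tables as CSV files (`mean_sample_sizes.csv`,
#' `prop_sample_sizes.csv`), the achieved criterion values
#' (`achieved.csv`) and a JSON manifest of all run parameters.
#'
#' @param tables An `"ssd_tables"` object from [ssd_tables()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ssd_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "ssd_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mean = file.path(dir, "mean_sample_sizes.csv"),
    prop = file.path(dir, "prop_sample_sizes.csv"),
    achieved = file.path(dir, "achieved.csv"),
    manifest = file.path(dir, "manifest.json"))
  utils::write.csv(tables$mean, paths["mean"], row.names = FALSE)
  utils::write.csv(tables$prop, paths["prop"], row.names = FALSE)
  utils::write.csv(tables$achieved, paths["achieved"], row.names = FALSE)
  manifest <- c(tables$parameters,
                list(package_version =
                       as.character(utils::packageVersion("ssdbayes")),
                     r_version = R.version.string))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Back-transform an interval length from the log scale
#'
#' A length-`l` interval for the mean of a log-transformed variable
#' corresponds, around a log-scale mean `mu`, to a length of
#' `l * exp(mu)` on the original scale.
#'
#' @param l Interval length on the log scale (>= 0).
#' @param mu Mean on the log scale.
#' @return Length on the original scale.
#' @examples
#' backtransform_length(0.2, 0.37)
#' @export
backtransform_length <- function(l, mu) {
  stopifnot(is.numeric(l), all(l >= 0), is.numeric(mu))
  l * exp(mu)
}
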