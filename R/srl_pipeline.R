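# Root-trait demonstration ----------------------------------------------
#
# Under cylindrical fine-root geometry, specific root length (length per
# unit dry mass) follows from root tissue density and diameter:
#
#   SRL = 4 / (pi * RTD * D^2),
#
# hence, on the log scale, the exact individual-level identity
#
#   ln SRL = ln(4/pi) - ln RTD - 2 ln D.
#
# Because the identity holds per individual, averaging the log values
# per species preserves it exactly: regressing species mean-log SRL on
# mean-log RTD and mean-log D returns intercept ln(4/pi), slopes -1 and
# -2, and R^2 = 1, for any data. Averaging the raw values first and
# then taking logs breaks the identity through the species-specific
# Jensen offsets, which is what this pipeline demonstrates side by
# side. The formula's constant 4/pi is dimensionless only under
# mutually consistent units (e.g. RTD in g cm^-3, D in cm, SRL in
# cm g^-1); unit consistency is the caller's responsibility.

#' Specific root length from tissue density and diameter
#'
#' @param rtd Root tissue density, `> 0` (mass per volume).
#' @param d Fine-root diameter, `> 0`; units must be consistent with
#'   `rtd`.
#' @return `4 / (pi * rtd * d^2)`, vectorised.
#' @examples
#' compute_srl(rtd = 4 / pi, d = 1)  # 1
#' @export
compute_srl <- function(rtd, d) {
  stopifnot(is.numeric(rtd), is.numeric(d))
  if (any(!is.finite(rtd)) || any(rtd <= 0)) {
    stop("rtd must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("d must be positive and finite", call. = FALSE)
  }
  4 / (pi * rtd * d^2)
}

#' Derive a per-individual SRL record from RTD and D records
#'
#' For every individual carrying both an RTD and a D measurement, adds
#' an SRL record computed by [compute_srl()]. Individuals missing either
#' trait are skipped; their count is reported in a message and attached
#' as attribute `"n_skipped"`.
#'
#' @param table A [trait_table()] containing traits `trait_rtd` and
#'   `trait_d`.
#' @param trait_rtd,trait_d,trait_srl Trait names (defaults `"RTD"`,
#'   `"D"`, `"SRL"`).
#' @return The augmented [trait_table()].
#' @export
derive_srl_column <- function(table, trait_rtd = "RTD", trait_d = "D",
                              trait_srl = "SRL") {
  if (!inherits(table, "trait_table")) table <- trait_table(table)
  if (!nrow(table)) stop("empty trait table", call. = FALSE)
  rtd <- table[table$trait == trait_rtd, c("species", "individual", "value")]
  d <- table[table$trait == trait_d, c("species", "individual", "value")]
  names(rtd)[3] <- "rtd"; names(d)[3] <- "d"
  both <- merge(rtd, d, by = c("species", "individual"))
  n_skipped <- length(unique(c(rtd$individual, d$individual))) - nrow(both)
  if (!nrow(both)) {
    stop(sprintf("no individual carries both '%s' and '%s'",
                 trait_rtd, trait_d), call. = FALSE)
  }
  if (n_skipped > 0) {
    message(sprintf(
      "derive_srl_column: skipped %d individual(s) missing %s or %s",
      n_skipped, trait_rtd, trait_d))
  }
  srl <- data.frame(species = both$species, individual = both$individual,
                    trait = trait_srl,
                    value = compute_srl(both$rtd, both$d),
                    stringsAsFactors = FALSE)
  out <- trait_table(rbind(as.data.frame(table), srl))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Run the full root-trait aggregation-order demonstration
#'
#' Derives SRL per individual, builds species-level log summaries of
#' SRL, RTD and D under both aggregation orders, and fits (a) the
#' trivariate regression of species log SRL on log RTD and log D under
#' each order and (b) the three pairwise regressions (SRL~RTD, SRL~D,
#' RTD~D) under each order. The transform-then-aggregate trivariate fit
#' recovers the geometric identity exactly (intercept ln(4/pi),
#' coefficient -1 on lnRTD, -2 on lnD, R^2 = 1); the
#' aggregate-then-transform fit generally does not.
#'
#' @param table A [trait_table()] with RTD and D records; SRL is derived
#'   internally (any pre-existing records named `trait_srl` are an
#'   error, to avoid mixing measured and derived values).
#' @param trait_rtd,trait_d,trait_srl Trait names.
#' @param disjoint If `TRUE`, species summaries of RTD use only the
#'   first half of each species' individuals and summaries of D only
#'   the second half (SRL still uses all shared individuals), emulating
#'   traits measured on different individual sets; the perfect-fit
#'   identity then holds only approximately. Default `FALSE`.
#' @return An object of class `srl_demo_report`: a list with
#'   `trivariate_transform_first` and `trivariate_transform_last`
#'   ([ols_fit()] results), `pairwise` (a named list of six fits,
#'   `"<response>~<predictor>.<order>"`), `species_count`,
#'   `individual_count`, and `summaries` (the per-species log summary
#'   table used for the fits).
#' @export
run_srl_demo <- function(table, trait_rtd = "RTD", trait_d = "D",
                         trait_srl = "SRL", disjoint = FALSE) {
  if (!inherits(table, "trait_table")) table <- trait_table(table)
  if (any(table$trait == trait_srl)) {
    stop(sprintf("table already contains trait '%s'; remove or rename it",
                 trait_srl), call. = FALSE)
  }
  aug <- derive_srl_column(table, trait_rtd, trait_d, trait_srl)
  if (disjoint) {
    aug <- .halve_individuals(aug, trait_rtd, trait_d)
  }
  log_t <- get_transform("log")
  s_srl <- summarize_trait(aug, trait_srl, log_t)
  s_rtd <- summarize_trait(aug, trait_rtd, log_t)
  s_d <- summarize_trait(aug, trait_d, log_t)
  common <- Reduce(intersect, list(s_srl$species, s_rtd$species,
                                   s_d$species))
  common <- sort(common)
  if (length(common) < 4L) {
    stop(sprintf("need >= 4 species with all three traits, found %d",
                 length(common)), call. = FALSE)
  }
  s_srl <- s_srl[match(common, s_srl$species), ]
  s_rtd <- s_rtd[match(common, s_rtd$species), ]
  s_d <- s_d[match(common, s_d$species), ]

  summaries <- data.frame(
    species = common,
    # transform-then-aggregate (mean of logs)
    lnSRL_tf = s_srl$mean_transformed,
    lnRTD_tf = s_rtd$mean_transformed,
    lnD_tf = s_d$mean_transformed,
    # aggregate-then-transform (log of means)
    lnSRL_tl = s_srl$transform_of_mean,
    lnRTD_tl = s_rtd$transform_of_mean,
    lnD_tl = s_d$transform_of_mean,
    stringsAsFactors = FALSE)

  tri_tf <- ols_fit(summaries$lnSRL_tf,
                    list(lnRTD = summaries$lnRTD_tf,
                         lnD = summaries$lnD_tf))
  tri_tl <- ols_fit(summaries$lnSRL_tl,
                    list(lnRTD = summaries$lnRTD_tl,
                         lnD = summaries$lnD_tl))

  cols <- c(SRL = "lnSRL", RTD = "lnRTD", D = "lnD")
  pairs <- list(c("SRL", "RTD"), c("SRL", "D"), c("RTD", "D"))
  pairwise <- list()
  for (pr in pairs) {
    for (ord in c("transform_first", "transform_last")) {
      suf <- if (ord == "transform_first") "_tf" else "_tl"
      resp <- summaries[[paste0(cols[pr[1]], suf)]]
      pred <- summaries[[paste0(cols[pr[2]], suf)]]
      key <- sprintf("%s~%s.%s", pr[1], pr[2], ord)
      pw <- list(pred); names(pw) <- paste0("ln", pr[2])
      pairwise[[key]] <- ols_fit(resp, pw)
    }
  }

  structure(
    list(trivariate_transform_first = tri_tf,
         trivariate_transform_last = tri_tl,
         pairwise = pairwise,
         species_count = length(common),
         individual_count = length(unique(
           aug$individual[aug$trait == trait_srl])),
         summaries = summaries),
    class = "srl_demo_report")
}

# restrict RTD records to the first half of each species' individuals
# and D records to the second half (SRL records untouched)
.halve_individuals <- function(table, trait_rtd, trait_d) {
  keep <- rep(TRUE, nrow(table))
  for (s in unique(table$species)) {
    ind <- sort(unique(table$individual[table$species == s]))
    half <- ceiling(length(ind) / 2)
    first <- ind[seq_len(half)]
    keep[table$species == s & table$trait == trait_rtd &
           !(table$individual %in% first)] <- FALSE
    keep[table$species == s & table$trait == trait_d &
           (table$individual %in% first)] <- FALSE
  }
  out <- table[keep, , drop = FALSE]
  class(out) <- class(table)
  out
}

#' @export
print.srl_demo_report <- function(x, ...) {
  cat(sprintf("<srl_demo_report> %d species, %d individuals with SRL\n",
              x$species_count, x$individual_count))
  cat("\ntrivariate, transform-then-aggregate:\n")
  print(x$trivariate_transform_first)
  cat("\ntrivariate, aggregate-then-transform:\n")
  print(x$trivariate_transform_last)
  cat("\npairwise slopes:\n")
  print(pairwise_table(x), row.names = FALSE)
  invisible(x)
}

#' Tabulate the six pairwise fits of a demo report
#'
#' @param report An `srl_demo_report`.
#' @return A data frame with columns `response`, `predictor`, `order`,
#'   `slope`, `se`, `r_squared` (the layout of a pairwise-regression
#'   summary table).
#' @export
pairwise_table <- function(report) {
  stopifnot(inherits(report, "srl_demo_report"))
  rows <- lapply(names(report$pairwise), function(key) {
    fit <- report$pairwise[[key]]
    parts <- strsplit(key, "[~.]")[[1L]]
    slope_name <- paste0("ln", parts[2])
    data.frame(response = parts[1], predictor = parts[2],
               order = parts[3],
               slope = unname(fit$coefficients[slope_name]),
               se = unname(fit$standard_errors[slope_name]),
               r_squared = fit$r_squared,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
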