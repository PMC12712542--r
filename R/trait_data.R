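# Individual-level trait tables and species-level summaries -------------
#
# The long format mirrors how individual records appear in large trait
# databases: one row per (species, individual, trait) with a numeric
# value. Values are unit-free by contract -- unit consistency is the
# caller's responsibility (a change of unit is a linear map and does not
# affect any Jensen-gap quantity, but the SRL pipeline needs mutually
# consistent length/mass units for its dimensionless constant).

#' Construct and validate an individual-level trait table
#'
#' @param df A data frame with columns `species`, `individual`, `trait`
#'   (character) and `value` (finite numeric). Enforced invariants:
#'   (species, individual, trait) triples are unique, values are finite,
#'   and an individual identifier belongs to exactly one species.
#' @return The validated data frame with class `trait_table`.
#' @export
trait_table <- function(df) {
  need <- c("species", "individual", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$species <- as.character(df$species)
  df$individual <- as.character(df$individual)
  df$trait <- as.character(df$trait)
  if (!is.numeric(df$value)) {
    stop("'value' column must be numeric", call. = FALSE)
  }
  if (anyNA(df$value) || any(!is.finite(df$value))) {
    stop("trait values must be finite; found NA/Inf", call. = FALSE)
  }
  key <- paste(df$species, df$individual, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf(
      "duplicated (species, individual, trait) triple: (%s, %s, %s)",
      d$species, d$individual, d$trait), call. = FALSE)
  }
  ind_sp <- unique(df[c("individual", "species")])
  if (anyDuplicated(ind_sp$individual)) {
    bad <- ind_sp$individual[duplicated(ind_sp$individual)][1L]
    stop(sprintf("individual '%s' is assigned to more than one species", bad),
         call. = FALSE)
  }
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read an individual-level trait CSV
#'
#' Reads a comma-delimited, UTF-8 file with a header row. Rows whose
#' value is missing are dropped with a message reporting the count;
#' non-numeric values and duplicated (species, individual, trait)
#' triples are errors.
#'
#' @param path Path to the CSV file.
#' @param col_species,col_individual,col_trait,col_value Names of the
#'   columns holding each field (defaults `species`, `individual`,
#'   `trait`, `value`).
#' @return A [trait_table()].
#' @export
read_trait_csv <- function(path,
                           col_species = "species",
                           col_individual = "individual",
                           col_trait = "trait",
                           col_value = "value") {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  cmap <- c(species = col_species, individual = col_individual,
            trait = col_trait, value = col_value)
  miss <- cmap[!cmap %in% names(raw)]
  if (length(miss)) {
    stop(sprintf("column(s) not found in %s: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(species = raw[[cmap["species"]]],
                   individual = raw[[cmap["individual"]]],
                   trait = raw[[cmap["trait"]]],
                   value_chr = raw[[cmap["value"]]],
                   stringsAsFactors = FALSE)
  blank <- is.na(df$value_chr) | trimws(df$value_chr) == ""
  if (any(blank)) {
    message(sprintf("read_trait_csv: dropped %d row(s) with missing values",
                    sum(blank)))
    df <- df[!blank, , drop = FALSE]
  }
  val <- suppressWarnings(as.numeric(df$value_chr))
  if (anyNA(val)) {
    i <- which(is.na(val))[1L]
    stop(sprintf("non-numeric value '%s' at data row %d of %s",
                 df$value_chr[i], i, path), call. = FALSE)
  }
  df$value <- val
  trait_table(df[c("species", "individual", "trait", "value")])
}

#' Summarise one trait per species under both aggregation orders
#'
#' For every species with at least one measurement of `trait`, computes
#' the sample size, the raw mean, the within-species variance, and the
#' species-level transformed value under both orders: `mean_transformed`
#' (transform-then-aggregate, mean of f(x_j)) and `transform_of_mean`
#' (aggregate-then-transform, f of the raw mean). By Jensen's inequality
#' the two differ whenever the transform is non-linear and the
#' within-species variance is positive.
#'
#' The stored variance is the population variance (divisor n) by
#' default, which is the convention the quadratic correction term uses;
#' set `var_convention = "sample"` for the n - 1 divisor.
#'
#' @param table A [trait_table()].
#' @param trait Name of the trait to summarise.
#' @param t A `trait_transform`.
#' @param var_convention `"population"` (divide by n, default) or
#'   `"sample"` (divide by n - 1; `NA` variance when n = 1 becomes 0).
#' @return A data frame of class `species_trait_summary` with columns
#'   `species`, `trait`, `n`, `mean_raw`, `var_raw_pop`,
#'   `mean_transformed`, `transform_of_mean`, one row per species,
#'   sorted by species identifier. Species with n = 1 are retained
#'   (their Jensen gap is exactly zero); their identifiers are attached
#'   as attribute `"singletons"`.
#' @export
summarize_trait <- function(table, trait, t,
                            var_convention = c("population", "sample")) {
  stopifnot(inherits(t, "trait_transform"))
  var_convention <- match.arg(var_convention)
  if (!inherits(table, "trait_table")) table <- trait_table(table)
  sub <- table[table$trait == trait, , drop = FALSE]
  if (!nrow(sub)) {
    stop(sprintf("trait '%s' not present in table", trait), call. = FALSE)
  }
  sp <- sort(unique(sub$species))
  out <- lapply(sp, function(s) {
    v <- sub$value[sub$species == s]
    bad <- v[!is.finite(v) | v <= t$domain_lo | v >= t$domain_hi]
    if (length(bad)) {
      stop(sprintf(
        "species '%s': value %g outside domain (%g, %g) of transform '%s'",
        s, bad[1L], t$domain_lo, t$domain_hi, t$name), call. = FALSE)
    }
    n <- length(v)
    m <- mean(v)
    vr <- if (var_convention == "population") {
      sum((v - m)^2) / n
    } else if (n > 1L) {
      sum((v - m)^2) / (n - 1L)
    } else 0
    data.frame(species = s, trait = trait, n = n, mean_raw = m,
               var_raw_pop = vr,
               mean_transformed = mean(t$forward(v)),
               transform_of_mean = t$forward(m),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "singletons") <- res$species[res$n == 1L]
  attr(res, "var_convention") <- var_convention
  class(res) <- c("species_trait_summary", "data.frame")
  res
}

#' Write species-level summaries to CSV
#'
#' One row per species x trait; numeric fields are written with 15
#' significant digits so a write/read cycle is lossless well past 12
#' significant digits.
#'
#' @param summaries A `species_trait_summary` data frame (or several
#'   row-bound together); must be non-empty.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  if (!is.data.frame(summaries) || !nrow(summaries)) {
    stop("no summaries to write", call. = FALSE)
  }
  df <- as.data.frame(summaries)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15L,
                                                scientific = FALSE,
                                                trim = TRUE))
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop(sprintf("cannot write %s: %s", path,
                                     conditionMessage(e)), call. = FALSE),
    warning = function(w) stop(sprintf("cannot write %s: %s", path,
                                       conditionMessage(w)), call. = FALSE))
  invisible(path)
}

#' Read species-level summaries written by [write_summary_csv()]
#'
#' @param path Path to the summary CSV.
#' @return A `species_trait_summary` data frame.
#' @export
read_summary_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("species_trait_summary", "data.frame")
  df
}
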