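# The 24-species pectoral fin morphometric table and its transforms.

#' Names of the eight pectoral fin muscles
#'
#' Four abductors (ABS, ABSp, ARRV, ABP), which pull the fin anteriorly, and
#' four adductors (ADS, ARRD, ADP, ADR), which pull it posteriorly. These are
#' the muscle mass columns of a trait table, in fixed order.
#' @export
muscle_names <- function() c("ABS", "ABSp", "ARRV", "ABP", "ADS", "ARRD", "ADP", "ADR")

#' Names of the four abductor muscles
#' @export
abductor_names <- function() c("ABS", "ABSp", "ARRV", "ABP")

validate_trait_table <- function(tab) {
  need <- c("species", "habitat", "SL", muscle_names())
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$species))
    stop("duplicate species in trait table")
  if (!all(tab$habitat %in% c("B", "L")))
    stop("habitat must be 'B' (benthic) or 'L' (limnetic)")
  m <- as.matrix(tab[, muscle_names()])
  if (anyNA(m) || any(m <= 0))
    stop("all eight muscle masses must be present and > 0")
  if (anyNA(tab$SL) || any(tab$SL <= 0))
    stop("SL must be present and > 0")
  if ("area" %in% names(tab) && any(!is.na(tab$area) & tab$area <= 0))
    stop("fin areas must be > 0 where present (missing is NA, not 0)")
  invisible(tab)
}

#' Load the built-in Malawi cichlid morphometric table
#'
#' Species-mean morphometrics for 24 Lake Malawi cichlid habitat specialists:
#' sample size, benthic/limnetic habitat, standard length SL (mm), wet masses
#' (mg) of the eight pectoral fin muscles, and pectoral fin area (mm^2; NA
#' for the 8 species whose fins could not be measured).
#'
#' @return a data frame with one row per species.
#' @export
load_builtin_table <- function() {
  path <- system.file("extdata", "malawi_pectoral_table1.csv",
                      package = "finphylo", mustWork = TRUE)
  read_trait_table(path)
}

#' Read a trait table from CSV
#'
#' Expects the same schema as the built-in table: columns `species, n,
#' habitat, SL, ABS, ABSp, ARRV, ABP, ADS, ARRD, ADP, ADR, area`, with
#' missing fin area as an empty cell.
#'
#' @param path CSV file path.
#' @return a validated data frame.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_trait_table(tab)
  tab
}

#' Per-species percent contribution of each muscle
#'
#' The contribution of each muscle's mass to the summed mass of all eight
#' pectoral muscles of that species, in percent. Rows sum to 100.
#'
#' @param table a trait table (see [load_builtin_table()]).
#' @return a matrix (species x 8 muscles) of percentages, with species as
#'   rownames.
#' @export
percent_contributions <- function(table) {
  validate_trait_table(table)
  m <- as.matrix(table[, muscle_names()])
  rownames(m) <- table$species
  100 * m / rowSums(m)
}

#' Summarize muscle percent contributions across species
#'
#' Unweighted means (mu), minima and maxima over species of the per-species
#' percentages, plus the mean summed percentage of the four abductors.
#'
#' @param table a trait table.
#' @return an object of class `muscle_summary` with fields `mean_pct`,
#'   `min_pct`, `max_pct` (named 8-vectors) and `abductor_total_pct`.
#' @export
summarize_percent <- function(table) {
  pct <- percent_contributions(table)
  structure(list(
    mean_pct = colMeans(pct),
    min_pct = apply(pct, 2, min),
    max_pct = apply(pct, 2, max),
    abductor_total_pct = mean(rowSums(pct[, abductor_names(), drop = FALSE])),
    n_species = nrow(pct)
  ), class = "muscle_summary")
}

#' @export
print.muscle_summary <- function(x, ...) {
  cat(sprintf("Percent contribution to total pectoral muscle mass (%d species)\n",
              x$n_species))
  for (m in names(x$mean_pct))
    cat(sprintf("  %-5s mu = %5.1f%%  Range: %.1f-%.1f%%\n",
                m, x$mean_pct[m], x$min_pct[m], x$max_pct[m]))
  cat(sprintf("  abductor total mu = %.1f%%\n", x$abductor_total_pct))
  invisible(x)
}

#' Linearize masses and areas to the dimension of length
#'
#' Muscle masses (mg, ~length^3) are replaced by their cube roots and fin
#' area (mm^2, ~length^2) by its square root, so all traits share SL's
#' dimension; a cube-rooted `total_mass` column (sum of the eight masses) is
#' added. SL is unchanged; missing areas stay missing.
#'
#' @param table a trait table.
#' @return the table with transformed trait columns and a `total_mass`
#'   column.
#' @export
linearize <- function(table) {
  validate_trait_table(table)
  out <- table
  m <- as.matrix(table[, muscle_names()])
  out$total_mass <- rowSums(m)^(1 / 3)
  out[, muscle_names()] <- m^(1 / 3)
  if ("area" %in% names(table)) {
    if (any(!is.na(table$area) & table$area < 0)) stop("negative fin area")
    out$area <- sqrt(table$area)
  }
  out
}
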