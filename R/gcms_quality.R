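#' The six key quality constituents of rose essential oil
#'
#' Quality grading of *Rosa damascena* essential oil rests on six volatiles:
#' phenyl ethyl alcohol, trans rose oxide, citronellol, nerol, geraniol and
#' geranial. The summed percent of these six constituents in a GC-MS profile
#' defines the oil's quality class (see [assign_quality_class()]).
#'
#' @return Character vector of the six constituent names, in conventional
#'   elution order.
#' @export
key_constituents <- function() {
  c(
    "phenyl ethyl alcohol", "trans rose oxide", "citronellol",
    "nerol", "geraniol", "geranial"
  )
}

#' Quality class labels
#'
#' Three ordered classes: `C1` (low), `C2` (middle), `C3` (high quality).
#' @return Character vector `c("C1", "C2", "C3")`.
#' @export
quality_classes <- function() c("C1", "C2", "C3")

# Canonical form used for constituent-name matching: case-insensitive,
# runs of whitespace collapsed. GC-MS tables are inconsistent about both.
normalize_constituent_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Read a GC-MS constituent table
#'
#' Reads a CSV with constituents as rows and genotypes as columns (the usual
#' layout of published essential-oil composition tables). Cells containing
#' `-`, `nd` or nothing denote "not detected" and are read as 0. Non-percent
#' annotation columns (e.g. a molecular formula) are dropped.
#'
#' @param path Path to the CSV file.
#' @return A `constituent_table`: data frame with a `constituent` character
#'   column followed by one numeric percent column per genotype.
#' @export
read_constituent_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"constituent" %in% names(raw)) {
    stop("constituent table must have a 'constituent' column", call. = FALSE)
  }
  keep <- setdiff(names(raw), c("constituent", "formula"))
  vals <- lapply(raw[keep], function(col) {
    col <- trimws(col)
    col[col %in% c("-", "", "nd", "ND", "NA")] <- "0"
    suppressWarnings(out <- as.numeric(col))
    if (anyNA(out)) stop("non-numeric percent entry in constituent table", call. = FALSE)
    out
  })
  tab <- data.frame(constituent = raw$constituent, vals, check.names = FALSE)
  validate_constituent_table(tab)
  tab
}

validate_constituent_table <- function(tab) {
  stopifnot(is.data.frame(tab), "constituent" %in% names(tab))
  geno <- setdiff(names(tab), "constituent")
  if (length(geno) == 0L) stop("constituent table has no genotype columns", call. = FALSE)
  for (g in geno) {
    v <- tab[[g]]
    if (!is.numeric(v)) stop("genotype column '", g, "' is not numeric", call. = FALSE)
    if (any(v < 0)) stop("negative percent in genotype '", g, "'", call. = FALSE)
    if (any(v > 100)) stop("percent > 100 in genotype '", g, "'", call. = FALSE)
  }
  invisible(tab)
}

#' Packaged GC-MS profile of ten Iranian rose genotypes
#'
#' Loads the bundled composition table of essential oils from ten
#' *Rosa damascena* genotypes (g1--g10), 56 identified volatiles, percent of
#' total peak area per genotype. These profiles are the reference inputs for
#' quality labelling: applying [label_dataset()] assigns g1--g4 to C1,
#' g5--g7 to C2 and g8--g10 to C3.
#'
#' @return A `constituent_table` data frame (see [read_constituent_table()]).
#' @export
rose_constituent_table <- function() {
  path <- system.file("extdata", "rose_constituents_gcms.csv",
    package = "rosenose", mustWork = TRUE
  )
  read_constituent_table(path)
}

#' Summed percent of the key quality constituents
#'
#' For one genotype profile, sums the percents of the six key constituents
#' (matched case-insensitively, whitespace-normalized). Constituents absent
#' from the profile count as 0.
#'
#' @param percents Named numeric vector: constituent name -> percent (0--100).
#' @param keys Character vector of constituent names to sum. Default the six
#'   key quality constituents.
#' @return Total percent (numeric scalar).
#' @export
total_key_constituents <- function(percents, keys = key_constituents()) {
  if (length(percents) == 0L) return(0)
  stopifnot(is.numeric(percents))
  if (any(percents < 0)) stop("negative constituent percent", call. = FALSE)
  nm <- normalize_constituent_name(names(percents))
  sum(percents[nm %in% normalize_constituent_name(keys)])
}

#' Assign oil quality class from the key-constituent total
#'
#' The grading rule: total below 10% is low quality (`C1`), between 10% and
#' 50% middle (`C2`), 50% or more high (`C3`). Boundaries are half-open
#' (`[0,10)`, `[10,50)`, `[50,Inf)`): a total of exactly 10 is C2 and exactly
#' 50 is C3. No observed profile sits on a boundary, so the convention does
#' not affect the reference genotypes.
#'
#' @param total Numeric vector of key-constituent totals (percent, >= 0).
#' @return Factor with levels `C1 < C2 < C3`.
#' @export
assign_quality_class <- function(total) {
  stopifnot(is.numeric(total))
  if (any(!is.finite(total))) stop("non-finite total", call. = FALSE)
  if (any(total < 0)) stop("negative total percent", call. = FALSE)
  cls <- ifelse(total >= 50, "C3", ifelse(total >= 10, "C2", "C1"))
  factor(cls, levels = quality_classes())
}

#' Label every genotype of a constituent table
#'
#' Computes each genotype's six-constituent total and applies the
#' 10%/50% quality rule.
#'
#' @param tab A `constituent_table` (see [read_constituent_table()]).
#' @param keys Constituent names to sum; default [key_constituents()].
#' @return Data frame with columns `genotype`, `total_percent`, `class`
#'   (factor C1/C2/C3), one row per genotype column of `tab`.
#' @export
label_dataset <- function(tab, keys = key_constituents()) {
  validate_constituent_table(tab)
  geno <- names(tab)[names(tab) != "constituent"]
  if (anyDuplicated(geno)) stop("duplicate genotype ids", call. = FALSE)
  totals <- vapply(geno, function(g) {
    p <- tab[[g]]
    names(p) <- tab$constituent
    total_key_constituents(p, keys)
  }, numeric(1))
  data.frame(
    genotype = geno,
    total_percent = unname(totals),
    class = assign_quality_class(unname(totals)),
    row.names = NULL
  )
}
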