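#' Adhesion-assay condition
#'
#' Identifies one cell-adhesion assay condition: the substratum material,
#' the yeast strain, the buffer pH and ionic strength, and whether the
#' cells were pre-treated with pronase. Optical density and settling time
#' are carried as metadata (the assays use a suspension at OD570 0.70
#' settled for 24 h).
#'
#' @param material Substratum, e.g. `"polystyrene"`, `"PET"`, `"glass"`,
#'   `"teflon"`.
#' @param strain Strain label, e.g. `"IMUFRJ"`, `"W29"`.
#' @param pH Buffer pH in \[0, 14\].
#' @param ionic_strength Molar ionic strength (> 0); the assays span 1e-4
#'   to 1e-1 M but any positive value is accepted.
#' @param treatment `"none"` or `"pronase"`.
#' @param od570 Cell-suspension optical density at 570 nm (metadata).
#' @param settle_hours Settling time, hours (metadata).
#' @return An `assay_condition`.
#' @export
assay_condition <- function(material, strain = "IMUFRJ", pH = 7,
                            ionic_strength = 0.1,
                            treatment = c("none", "pronase"),
                            od570 = 0.70, settle_hours = 24) {
  treatment <- match.arg(treatment)
  if (!is.finite(pH) || pH < 0 || pH > 14)
    stop("pH must lie in [0, 14]")
  if (!is.finite(ionic_strength) || ionic_strength <= 0)
    stop("ionic_strength must be positive (molar)")
  structure(list(material = material, strain = strain, pH = pH,
                 ionic_strength = ionic_strength, treatment = treatment,
                 od570 = od570, settle_hours = settle_hours),
            class = "assay_condition")
}

condition_key <- function(cond, exclude = character(0)) {
  f <- c("material", "strain", "pH", "ionic_strength", "treatment")
  f <- setdiff(f, exclude)
  paste(vapply(f, function(x) format(cond[[x]], scientific = TRUE),
               character(1)), collapse = "|")
}

#' Adhesion record: condition plus replicate summary
#'
#' @param condition An [assay_condition()].
#' @param summary A [replicate_summary()] of coverage fractions.
#' @return An `adhesion_record`.
#' @export
adhesion_record <- function(condition, summary) {
  if (!inherits(condition, "assay_condition"))
    stop("'condition' must be an assay_condition")
  if (!inherits(summary, "replicate_summary"))
    stop("'summary' must be a replicate_summary")
  structure(list(condition = condition, summary = summary),
            class = "adhesion_record")
}

records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r)
    data.frame(material = r$condition$material, strain = r$condition$strain,
               pH = r$condition$pH,
               ionic_strength = r$condition$ionic_strength,
               treatment = r$condition$treatment,
               mean_coverage = r$summary$mean_coverage,
               sd_coverage = r$summary$sd_coverage,
               n_images = r$summary$n_images, stringsAsFactors = FALSE)))
}

#' Read adhesion records from CSV
#'
#' Columns: `material,strain,pH,ionic_strength,treatment,mean_coverage,
#' sd_coverage,n_images` (sd may be empty/NA when unknown, as for published
#' tables that print means only).
#'
#' @param path CSV path.
#' @return List of `adhesion_record` objects.
#' @export
read_adhesion_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    adhesion_record(
      assay_condition(df$material[i], df$strain[i], as.numeric(df$pH[i]),
                      as.numeric(df$ionic_strength[i]),
                      if (is.na(df$treatment[i]) || df$treatment[i] == "")
                        "none" else df$treatment[i]),
      replicate_summary(df$mean_coverage[i],
                        if (is.null(df$sd_coverage)) NA_real_
                        else df$sd_coverage[i],
                        if (is.null(df$n_images) || is.na(df$n_images[i]))
                          1L else df$n_images[i])))
}

#' Write adhesion records to CSV
#' @param records List of `adhesion_record` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_adhesion_records <- function(records, path) {
  df <- records_to_df(records)
  # %.17g keeps doubles bit-exact through the CSV round trip
  for (col in c("pH", "ionic_strength", "mean_coverage", "sd_coverage"))
    df[[col]] <- ifelse(is.na(df[[col]]), NA, sprintf("%.17g", df[[col]]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a factorial condition table of mean coverages
#'
#' Pivots adhesion records into a rectangular table with one assay factor
#' (or factor combination) on the rows and another on the columns, in the
#' style of published adhesion tables (e.g. pH rows against
#' material-by-strain columns). Cells hold the mean coverage; missing
#' factorial cells are `NA`. The long form round-trips losslessly.
#'
#' @param records List of `adhesion_record` objects.
#' @param rows Character vector of factor names for the rows (from
#'   `material`, `strain`, `pH`, `ionic_strength`, `treatment`).
#' @param columns Character vector of factor names for the columns.
#' @return List with `wide` (data frame of means, first column(s) the row
#'   factor), `wide_sd` (matching sd table), and `long` (the flat record
#'   data frame).
#' @export
assemble_table <- function(records, rows = "pH",
                           columns = c("material", "strain")) {
  if (!length(records)) stop("no records supplied")
  df <- records_to_df(records)
  factors <- c("material", "strain", "pH", "ionic_strength", "treatment")
  stopifnot(all(rows %in% factors), all(columns %in% factors))
  key <- do.call(paste, c(df[factors], sep = "|"))
  if (anyDuplicated(key))
    stop("duplicate condition(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rkey <- do.call(paste, c(df[rows], sep = " / "))
  ckey <- do.call(paste, c(df[columns], sep = " / "))
  rlev <- unique(rkey); clev <- unique(ckey)
  wide <- matrix(NA_real_, length(rlev), length(clev),
                 dimnames = list(rlev, clev))
  wide_sd <- wide
  wide[cbind(match(rkey, rlev), match(ckey, clev))] <- df$mean_coverage
  wide_sd[cbind(match(rkey, rlev), match(ckey, clev))] <- df$sd_coverage
  wide_df <- data.frame(row = rlev, wide, check.names = FALSE,
                        stringsAsFactors = FALSE)
  names(wide_df)[1] <- paste(rows, collapse = " / ")
  sd_df <- data.frame(row = rlev, wide_sd, check.names = FALSE,
                      stringsAsFactors = FALSE)
  names(sd_df)[1] <- names(wide_df)[1]
  list(wide = wide_df, wide_sd = sd_df, long = df)
}

#' Contrast coverage before and after a treatment
#'
#' Compares two adhesion records identical in every factor except the
#' treatment: the after-minus-before difference of mean coverages, a pooled
#' sd by root-sum-of-squares, the after/before ratio, and a
#' `strong_reduction` flag set when the coverage falls by more than twice
#' the pooled sd. No formal hypothesis test is attached: source tables
#' report no test, so the flag is a conservative, assumption-light
#' convention.
#'
#' @param before `adhesion_record` for the untreated condition.
#' @param after `adhesion_record` for the treated condition.
#' @return List with `difference`, `pooled_sd`, `ratio`,
#'   `strong_reduction`, and the two records.
#' @examples
#' cond <- function(tr) assay_condition("polystyrene", pH = 7,
#'   ionic_strength = 1e-4, treatment = tr)
#' treatment_contrast(
#'   adhesion_record(cond("none"), replicate_summary(0.78, 0.08, 3)),
#'   adhesion_record(cond("pronase"), replicate_summary(0.05, 0.01, 3)))
#' @export
treatment_contrast <- function(before, after) {
  stopifnot(inherits(before, "adhesion_record"),
            inherits(after, "adhesion_record"))
  kb <- condition_key(before$condition, exclude = "treatment")
  ka <- condition_key(after$condition, exclude = "treatment")
  if (kb != ka)
    stop("records differ in non-treatment factors: '", kb, "' vs '", ka, "'")
  d <- after$summary$mean_coverage - before$summary$mean_coverage
  sds <- c(before$summary$sd_coverage, after$summary$sd_coverage)
  pooled <- if (any(is.na(sds))) NA_real_ else sqrt(sum(sds^2))
  ratio <- if (before$summary$mean_coverage == 0) NA_real_
           else after$summary$mean_coverage / before$summary$mean_coverage
  structure(
    list(difference = d, pooled_sd = pooled, ratio = ratio,
         strong_reduction = !is.na(pooled) && d < 0 && abs(d) > 2 * pooled,
         before = before, after = after),
    class = "treatment_contrast")
}

#' @export
print.treatment_contrast <- function(x, ...) {
  cat(sprintf(
    "<treatment_contrast> diff %+.3f (pooled sd %s, ratio %s)%s\n",
    x$difference,
    ifelse(is.na(x$pooled_sd), "NA", sprintf("%.4f", x$pooled_sd)),
    ifelse(is.na(x$ratio), "NA", sprintf("%.3f", x$ratio)),
    if (isTRUE(x$strong_reduction)) " STRONG REDUCTION" else ""))
  invisible(x)
}

#' Coverage profile along ionic strength
#'
#' Orders records that differ only in ionic strength and reports whether
#' adhesion drops at the highest strength (coverage there below the mean of
#' the remaining strengths) -- the steric-inhibition signature seen at
#' 0.1 M.
#'
#' @param records List of `adhesion_record` objects sharing material,
#'   strain, pH and treatment; at least two distinct ionic strengths.
#' @return List with `profile` (data frame `ionic_strength`,
#'   `mean_coverage`, sorted ascending) and `drop_at_highest` (logical).
#' @export
ionic_strength_profile <- function(records) {
  if (length(records) < 2)
    stop("need records at >= 2 ionic strengths")
  keys <- vapply(records, function(r)
    condition_key(r$condition, exclude = "ionic_strength"), character(1))
  if (length(unique(keys)) > 1)
    stop("records differ in factors other than ionic strength")
  is_ <- vapply(records, function(r) r$condition$ionic_strength, numeric(1))
  if (anyDuplicated(is_)) stop("duplicate ionic strengths")
  cov <- vapply(records, function(r) r$summary$mean_coverage, numeric(1))
  o <- order(is_)
  prof <- data.frame(ionic_strength = is_[o], mean_coverage = cov[o])
  n <- nrow(prof)
  drop <- prof$mean_coverage[n] < mean(prof$mean_coverage[-n])
  list(profile = prof, drop_at_highest = drop)
}
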