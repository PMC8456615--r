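# Clinical response labeling: merge Xena- and cBioPortal-style annotation
# rows into binary responded/progressive labels, restricted to
# chemotherapy-treated tumors.

norm_str <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("\\s+", " ", x)
}

# vocabularies after normalization; disease-free status is additionally
# matched with whitespace removed ("diseasefree" vs "disease free")
.resp_responded_xena <- norm_str(c("Complete response", "Partial response"))
.resp_progressive_xena <- norm_str(c("Radiographic progressive disease",
                                     "Clinical progressive disease",
                                     "Stable disease"))

#' Read a clinical annotation table
#'
#' Parses a TSV in either the Xena dialect (`submitter_id.samples`,
#' `therapy_type`, `measure_of_response`) or the cBioPortal dialect
#' (`Sample_ID`, `Disease.Free.Status`, `Pharmaceutical.Therapy.Indicator`),
#' auto-detected from the header, into the normalized record form consumed
#' by [assign_response_labels()].
#'
#' @param path TSV path (or a `data.frame` already in one of the dialects).
#' @return A `data.frame` of clinical records with columns `sample_id`,
#'   `source`, `therapy`, `response`.
#' @export
read_clinical_table <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "", fill = TRUE,
                      na.strings = c("NA", ""))
  cn <- names(df)
  if (all(c("submitter_id.samples", "therapy_type",
            "measure_of_response") %in% cn)) {
    data.frame(sample_id = as.character(df[["submitter_id.samples"]]),
               source = "xena",
               therapy = as.character(df[["therapy_type"]]),
               response = as.character(df[["measure_of_response"]]),
               stringsAsFactors = FALSE)
  } else if (all(c("Sample_ID", "Disease.Free.Status",
                   "Pharmaceutical.Therapy.Indicator") %in% cn)) {
    data.frame(sample_id = as.character(df[["Sample_ID"]]),
               source = "cbioportal",
               therapy = as.character(df[["Pharmaceutical.Therapy.Indicator"]]),
               response = as.character(df[["Disease.Free.Status"]]),
               stringsAsFactors = FALSE)
  } else {
    stop("unrecognized clinical table dialect; columns found: ",
         paste(cn, collapse = ", "))
  }
}

label_one_record <- function(source, therapy, response) {
  therapy <- norm_str(therapy)
  response <- norm_str(response)
  chemo <- if (source == "xena") identical(therapy, "chemotherapy")
           else identical(therapy, "yes")
  if (!isTRUE(chemo) || is.na(response) || !nzchar(response)) return(NA_integer_)
  if (source == "xena") {
    if (response %in% .resp_responded_xena) return(0L)
    if (response %in% .resp_progressive_xena) return(1L)
  } else {
    nospace <- gsub(" ", "", response)
    if (nospace == "diseasefree") return(0L)
    if (nospace == "recurred/progressed") return(1L)
  }
  NA_integer_
}

#' Assign responded/progressive labels from clinical records
#'
#' Implements the clinical labeling rules: a tumor is labeled *responded*
#' (`y = 0`) if a chemotherapy-treated record shows a complete or partial
#' response (Xena) or a disease-free status (cBioPortal); *progressive*
#' (`y = 1`) if such a record shows radiographic/clinical progressive
#' disease or stable disease (Xena) or recurred/progressed status
#' (cBioPortal). Records without chemotherapy, or with no response value,
#' leave a tumor unlabeled. Matching is case-insensitive on trimmed,
#' whitespace-collapsed values. When multiple records for one sample
#' disagree, progression wins (the conservative clinical reading).
#'
#' @param records a records `data.frame` from [read_clinical_table()], a raw
#'   dialect table, or a list of such tables (e.g., one per source).
#' @return A `data.frame` with columns `sample_id`, `y` (`0`, `1`, or `NA`
#'   for unlabeled) and `provenance` (which sources decided the label),
#'   one row per distinct sample, in first-appearance order.
#' @examples
#' recs <- data.frame(sample_id = c("a", "a", "b"), source = "xena",
#'                    therapy = "Chemotherapy",
#'                    response = c("Partial response", "Stable disease", ""))
#' assign_response_labels(recs)  # "a" is progressive: progression dominates
#' @export
assign_response_labels <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, read_clinical_table))
  if (!all(c("sample_id", "source", "therapy", "response") %in% names(records)))
    records <- read_clinical_table(records)
  if (nrow(records) && any(!nzchar(records$sample_id) | is.na(records$sample_id)))
    stop("clinical records contain empty sample ids")
  per_row <- mapply(label_one_record, records$source, records$therapy,
                    records$response, USE.NAMES = FALSE)
  ids <- unique(records$sample_id)
  y <- integer(length(ids))
  prov <- character(length(ids))
  for (i in seq_along(ids)) {
    rows <- which(records$sample_id == ids[i])
    lab <- per_row[rows]
    deciding <- rows[!is.na(lab)]
    if (any(lab == 1L, na.rm = TRUE)) {          # progression-dominant merge
      y[i] <- 1L
      deciding <- rows[which(!is.na(lab) & lab == 1L)]
    } else if (any(lab == 0L, na.rm = TRUE)) {
      y[i] <- 0L
      deciding <- rows[which(!is.na(lab) & lab == 0L)]
    } else {
      y[i] <- NA_integer_
      deciding <- integer(0)
    }
    prov[i] <- if (length(deciding))
      paste(sort(unique(records$source[deciding])), collapse = "+") else ""
  }
  data.frame(sample_id = ids, y = y, provenance = prov,
             stringsAsFactors = FALSE)
}

#' Summarize label counts, labeled proportion and class balance
#'
#' @param labels a `data.frame` from [assign_response_labels()], or a vector
#'   of labels (`0`/`1`/`NA`).
#' @return A one-row `data.frame`: `n_total`, `n_labeled`, `n_responded`,
#'   `n_progressive`, `labeled_proportion`, `balance_ratio`
#'   (responded/progressive; `Inf` when no progressive samples).
#' @export
class_balance_summary <- function(labels) {
  y <- if (is.data.frame(labels)) labels$y else labels
  n <- length(y)
  n0 <- sum(y == 0L, na.rm = TRUE)
  n1 <- sum(y == 1L, na.rm = TRUE)
  data.frame(n_total = n, n_labeled = n0 + n1,
             n_responded = n0, n_progressive = n1,
             labeled_proportion = if (n) (n0 + n1) / n else NA_real_,
             balance_ratio = if (n1 > 0) n0 / n1 else Inf)
}
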