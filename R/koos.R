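KOOS_SUBSCALES <- c("symptoms", "pain", "adl", "sport", "qol")

#' KOOS item table
#'
#' The 42 items of the Knee injury and Osteoarthritis Outcome Score,
#' partitioned into five subscales: pain (P1-P9), symptoms (S1-S7),
#' activities of daily living (A1-A17), sport/recreation (SP1-SP5) and
#' knee-related quality of life (Q1-Q4). Each item is answered on a 0-4
#' Likert scale (0 = no problems, 4 = extreme problems).
#'
#' @return data.frame with columns `item_id` and `subscale`.
#' @export
koos_items <- function() {
  data.frame(
    item_id = c(paste0("P", 1:9), paste0("S", 1:7), paste0("A", 1:17),
                paste0("SP", 1:5), paste0("Q", 1:4)),
    subscale = rep(c("pain", "symptoms", "adl", "sport", "qol"),
                   times = c(9, 7, 17, 5, 4)))
}

#' KOOS questionnaire response
#'
#' @param answers numeric vector of 42 item answers in 0-4 (NA = missing),
#'   either named by item id (`P1`...`Q4`) or in [koos_items()] order.
#' @return An object of class `koos_response` (named 42-vector).
#' @export
koos_response <- function(answers) {
  items <- koos_items()$item_id
  a <- answers
  if (!is.null(names(a))) {
    if (!setequal(names(a), items))
      stop("answer names must be exactly the 42 KOOS item ids")
    a <- a[items]
  } else {
    if (length(a) != 42) stop("a KOOS response has 42 items, got ", length(a))
    names(a) <- items
  }
  bad <- !is.na(a) & (a < 0 | a > 4 | a != round(a))
  if (any(bad))
    stop("invalid KOOS answers (must be integers 0-4 or NA): ",
         paste(names(a)[bad], collapse = ", "))
  structure(as.numeric(a), names = items, class = "koos_response")
}

#' Score a KOOS response into the five subscales
#'
#' Per subscale: if at least 50% of its items are answered, the score is
#' `100 - mean(answered items) * 25`, rounded to one decimal (0 = extreme
#' problems, 100 = no problems); otherwise the subscale is missing. The
#' mean-of-answered rule is the standard KOOS missing-item convention.
#'
#' @param response A [koos_response()] (or a vector accepted by it).
#' @return An object of class `koos_scores`: named list with `symptoms`,
#'   `pain`, `adl`, `sport`, `qol`, each in \[0, 100\] or NA.
#' @export
#' @examples
#' score_koos(rep(0, 42))  # all subscales 100
score_koos <- function(response) {
  if (!inherits(response, "koos_response")) response <- koos_response(response)
  it <- koos_items()
  out <- lapply(KOOS_SUBSCALES, function(s) {
    a <- response[it$item_id[it$subscale == s]]
    if (mean(!is.na(a)) >= 0.5)
      round(100 - mean(a, na.rm = TRUE) * 25, 1)
    else NA_real_
  })
  names(out) <- KOOS_SUBSCALES
  structure(out, class = "koos_scores")
}

#' @export
print.koos_scores <- function(x, ...) {
  cat("<koos_scores>",
      paste(sprintf("%s %.1f", KOOS_SUBSCALES, unlist(x)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Score a matrix of KOOS responses
#'
#' Vectorized [score_koos()] for item-level cohort data.
#'
#' @param answers n x 42 matrix (columns in [koos_items()] order or named).
#' @return n x 5 matrix of subscale scores.
#' @export
score_koos_matrix <- function(answers) {
  a <- as.matrix(answers)
  items <- koos_items()
  if (!is.null(colnames(a))) a <- a[, items$item_id, drop = FALSE]
  if (ncol(a) != 42) stop("expected 42 item columns")
  if (any(!is.na(a) & (a < 0 | a > 4)))
    stop("invalid KOOS answers (must be in 0-4 or NA)")
  out <- sapply(KOOS_SUBSCALES, function(s) {
    cols <- which(items$subscale == s)
    sub <- a[, cols, drop = FALSE]
    answered <- rowMeans(!is.na(sub))
    sc <- round(100 - rowMeans(sub, na.rm = TRUE) * 25, 1)
    sc[answered < 0.5] <- NA_real_
    sc
  })
  colnames(out) <- KOOS_SUBSCALES
  out
}

#' KOOS subscale values imputed at conversion to total knee arthroplasty
#'
#' Patients converted to TKA are assigned fixed average subscale values
#' representing their state just before conversion (derived from a prior
#' arthroplasty cohort): symptoms 52, pain 45, ADL 55, sport 16, QoL 27.
#' The imputation overrides any completed questionnaire.
#'
#' @param record list or one-row data.frame with a logical `tka` element.
#' @return A `koos_scores` object with the imputed values.
#' @export
#' @examples
#' impute_tka_scores(list(tka = TRUE))$symptoms  # 52
impute_tka_scores <- function(record) {
  tka <- record$tka
  if (is.null(tka) || length(tka) != 1 || is.na(tka) || !isTRUE(as.logical(tka)))
    stop("TKA imputation requires a record flagged as converted to TKA")
  structure(list(symptoms = 52, pain = 45, adl = 55, sport = 16, qol = 27),
            class = "koos_scores")
}

#' Read item-level KOOS responses from CSV
#'
#' CSV columns: `case_id`, `item_id`, `answer`.
#'
#' @param path CSV path.
#' @return data.frame with `case_id` and one column per subscale score.
#' @export
read_koos_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("case_id", "item_id", "answer") %in% names(d)))
    stop("KOOS CSV must have columns case_id,item_id,answer")
  ids <- unique(d$case_id)
  items <- koos_items()$item_id
  m <- matrix(NA_real_, length(ids), 42, dimnames = list(NULL, items))
  for (i in seq_along(ids)) {
    s <- d[d$case_id == ids[i], ]
    m[i, as.character(s$item_id)] <- s$answer
  }
  cbind(data.frame(case_id = ids), as.data.frame(score_koos_matrix(m)))
}
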