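# Ensemble enzyme (EC) annotation: all profile-tool (DETECT-like) calls are
# kept, plus the ECs on which the PRIAM-like and similarity-search (DIAMOND)
# sources agree, under a low or high stringency policy. Multi-EC targets are
# validated against a curated co-occurrence pair table.

EC_REGEX <- "^\\d+\\.[\\d-]+\\.[\\d-]+\\.[\\d-]+$"

assert_valid_ec <- function(ec) {
  bad <- !grepl(EC_REGEX, ec, perl = TRUE)
  if (any(bad)) stop("malformed EC number: ", ec[bad][1])
  invisible(ec)
}

#' Stringency policy for the enzyme ensemble
#'
#' The low-stringency report accepts PRIAM-and-DIAMOND agreements with a
#' DIAMOND e-value below 1e-5; the high-stringency report requires e-value
#' below 1e-10 together with a PRIAM probability of at least 0.5.
#'
#' @param mode `"low"` or `"high"`.
#' @return List with `mode`, `evalue_max`, `priam_prob_min` (NA in low mode).
#' @export
stringency_policy <- function(mode = c("low", "high")) {
  mode <- match.arg(mode)
  if (mode == "low")
    list(mode = "low", evalue_max = 1e-5, priam_prob_min = NA_real_)
  else
    list(mode = "high", evalue_max = 1e-10, priam_prob_min = 0.5)
}

#' Read a DETECT/PRIAM-style EC prediction TSV
#'
#' Expected columns: target id, EC, probability. A header line is detected
#' and skipped.
#'
#' @param path TSV path.
#' @return `data.table` (`target_id`, `ec`, `probability`).
#' @export
read_ec_predictions <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "\t")
  if (ncol(dt) < 3L) stop("EC prediction file needs 3 columns")
  data.table::setnames(dt, 1:3, c("target_id", "ec", "probability"))
  dt[, probability := as.numeric(probability)]
  assert_valid_ec(dt$ec)
  dt
}

#' Read a DIAMOND EC source: m8 report plus a protein-to-EC map
#'
#' Each m8 subject is translated to its EC(s); per (target, EC) the lowest
#' e-value is retained.
#'
#' @param m8_path BLAST-tabular report of targets vs an EC-labelled protein set.
#' @param protein_ec_map_path Two-column TSV (protein id, EC).
#' @return `data.table` (`target_id`, `ec`, `evalue`).
#' @export
read_diamond_ec <- function(m8_path, protein_ec_map_path) {
  m8 <- read_m8(m8_path)
  pe <- data.table::fread(protein_ec_map_path, header = FALSE, sep = "\t",
                          col.names = c("protein_id", "ec"))
  assert_valid_ec(pe$ec)
  dt <- merge(m8[, .(target_id = query_id, protein_id = subject_id, evalue)],
              pe, by = "protein_id", allow.cartesian = TRUE)
  if (nrow(dt) == 0L)
    return(data.table::data.table(target_id = character(), ec = character(),
                                  evalue = numeric()))
  dt[, .(evalue = min(evalue)), by = c("target_id", "ec")]
}

#' Load a co-occurrence database of valid EC pairs
#'
#' Two-column TSV of EC pairs, order-insensitive; self-pairs are rejected.
#'
#' @param path TSV path.
#' @return Character vector of canonical `"ec1|ec2"` keys (sorted within pair),
#'   class `ec_pair_db`.
#' @export
load_ec_pair_db <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("ec1", "ec2"))
  assert_valid_ec(c(dt$ec1, dt$ec2))
  if (any(dt$ec1 == dt$ec2)) stop("co-occurrence DB contains a self-pair")
  keys <- unique(ec_pair_key(dt$ec1, dt$ec2))
  structure(keys, class = "ec_pair_db")
}

ec_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Merge the three EC prediction sources for every target
#'
#' Result per target = all DETECT ECs, united with ECs predicted by both
#' PRIAM and DIAMOND that satisfy the policy (DIAMOND e-value below the
#' cutoff; in high stringency also PRIAM probability >= 0.5). The unified
#' score per EC is the DETECT probability when present, else the PRIAM
#' probability, else `1 - min(evalue, 1)`.
#'
#' @param detect,priam `data.table`s (`target_id`, `ec`, `probability`).
#' @param diamond `data.table` (`target_id`, `ec`, `evalue`).
#' @param policy A [stringency_policy()].
#' @return `data.table` (`target_id`, `ec`, `sources`, `score`).
#' @export
merge_predictions <- function(detect, priam, diamond,
                              policy = stringency_policy("low")) {
  empty <- data.table::data.table(target_id = character(), ec = character(),
                                  sources = character(), score = numeric())
  norm <- function(dt, cols) {
    if (is.null(dt) || nrow(dt) == 0L)
      return(data.table::as.data.table(
        stats::setNames(list(character(), character(), numeric()), cols)))
    assert_valid_ec(dt$ec)
    dt
  }
  detect <- norm(detect, c("target_id", "ec", "probability"))
  priam <- norm(priam, c("target_id", "ec", "probability"))
  diamond <- norm(diamond, c("target_id", "ec", "evalue"))

  agree <- merge(priam[, .(target_id, ec, priam_prob = probability)],
                 diamond[, .(target_id, ec, evalue)],
                 by = c("target_id", "ec"))
  agree <- agree[evalue < policy$evalue_max]
  if (!is.na(policy$priam_prob_min))
    agree <- agree[priam_prob >= policy$priam_prob_min]

  d <- detect[, .(target_id, ec, sources = "DETECT", score = probability)]
  a <- agree[, .(target_id, ec, sources = "PRIAM+DIAMOND",
                 score = ifelse(is.na(priam_prob), 1 - pmin(evalue, 1),
                                priam_prob))]
  out <- data.table::rbindlist(list(d, a))
  if (nrow(out) == 0L) return(empty)
  # DETECT score takes precedence when both routes call the same EC
  out <- out[, .(sources = paste(unique(sources), collapse = "+"),
                 score = if ("DETECT" %in% sources) score[sources == "DETECT"][1]
                         else score[1]),
             by = c("target_id", "ec")]
  data.table::setorderv(out, c("target_id", "ec"))
  out
}

#' Validate a target's EC set against the co-occurrence database
#'
#' Singletons pass unchanged. Sets larger than two are first reduced to the
#' two highest-scoring ECs (ties broken by lexicographic EC order); if the
#' remaining pair is not a known co-occurring pair, only the higher-scoring
#' EC survives.
#'
#' @param ecs Character vector of EC numbers for one target.
#' @param scores Numeric scores aligned with `ecs` (NA treated as 0).
#' @param db An `ec_pair_db` from [load_ec_pair_db()].
#' @return Character vector of surviving ECs (length <= 2).
#' @export
filter_cooccurrence <- function(ecs, scores, db) {
  stopifnot(length(ecs) == length(scores))
  if (length(ecs) <= 1L) return(ecs)
  scores[is.na(scores)] <- 0
  ord <- order(-scores, ecs)
  ecs <- ecs[ord]; scores <- scores[ord]
  ecs <- ecs[1:2]; scores <- scores[1:2]
  if (ec_pair_key(ecs[1], ecs[2]) %in% unclass(db)) ecs else ecs[1]
}

#' Build and write the low- and high-stringency EC reports
#'
#' Both reports contain all DETECT calls; the low report adds
#' PRIAM-and-DIAMOND agreements at e-value < 1e-5, the high report at
#' e-value < 1e-10 with PRIAM probability >= 0.5. Co-occurrence filtering is
#' applied identically to both, after which the high report must be a subset
#' of the low report for every target.
#'
#' @param detect,priam,diamond Prediction tables as in [merge_predictions()].
#' @param pair_db An `ec_pair_db`.
#' @param low_path,high_path Output TSV paths (optional; `NULL` skips writing).
#' @return List with `low` and `high` annotation `data.table`s
#'   (`target_id`, `ec`, `sources`, `score`) and `n_unique_ec` counts.
#' @export
ec_reports <- function(detect, priam, diamond, pair_db,
                       low_path = NULL, high_path = NULL) {
  one <- function(mode) {
    merged <- merge_predictions(detect, priam, diamond, stringency_policy(mode))
    if (nrow(merged) == 0L) return(merged)
    merged[, {
      keep <- filter_cooccurrence(ec, score, pair_db)
      .SD[ec %in% keep]
    }, by = "target_id"]
  }
  low <- one("low")
  high <- one("high")
  # subset invariant: every high-report (target, ec) must appear in low
  if (nrow(high)) {
    key_low <- paste(low$target_id, low$ec)
    if (!all(paste(high$target_id, high$ec) %in% key_low))
      stop("invariant violated: high-stringency report not a subset of low")
  }
  if (!is.null(low_path)) data.table::fwrite(low, low_path, sep = "\t")
  if (!is.null(high_path)) data.table::fwrite(high, high_path, sep = "\t")
  list(low = low, high = high,
       n_unique_ec = c(low = length(unique(low$ec)),
                       high = length(unique(high$ec))))
}
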