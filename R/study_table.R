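# Study tables: per-patient paired scores, demographics, Ashworth
# spasticity scores and the 4-level Likert questionnaire; cohort
# eligibility filtering; questionnaire summaries; and synthetic
# generators standing in for the unreleased patient data.

LIKERT_LEVELS <- c("strongly_disagree", "disagree", "agree", "strongly_agree")
N_LIKERT_ITEMS <- 11L

likert_cols <- function() paste0("q", seq_len(N_LIKERT_ITEMS))

#' Validate a study table
#'
#' One row per patient: `patient_id`, `bbt_score`, `arbbt_score`
#' (non-negative integers, blocks transferred), `age` (years), `sex`,
#' `months_since_diagnosis`, `ashworth` (ordinal 0-4), `etiology`,
#' `comorbidity` (free-text labels, `;`-separated, empty for none) and
#' eleven questionnaire items `q1`-`q11` on the 4-level scale
#' strongly_disagree / disagree / agree / strongly_agree.
#'
#' @param df Data.frame to validate.
#' @return `df`, invisibly, or an error naming the offending field.
#' @export
validate_study_table <- function(df) {
  needed <- c("patient_id", "bbt_score", "arbbt_score", "age", "sex",
              "months_since_diagnosis", "ashworth", "etiology", "comorbidity",
              likert_cols())
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("study table missing field(s): ", paste(missing, collapse = ", "))
  if (any(df$bbt_score < 0) || any(df$arbbt_score < 0))
    stop("scores must be non-negative")
  if (any(df$months_since_diagnosis < 0))
    stop("months_since_diagnosis must be non-negative")
  if (any(!df$ashworth %in% 0:4))
    stop("ashworth must be an integer on the 0-4 scale")
  for (q in likert_cols())
    if (any(!df[[q]] %in% LIKERT_LEVELS))
      stop("invalid response level in ", q)
  invisible(df)
}

#' Read / write a study table as CSV
#'
#' @param path CSV path.
#' @return The validated study table data.frame.
#' @export
read_study_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_study_table(df)
  df
}

#' @rdname read_study_table
#' @param df A study table data.frame.
#' @export
write_study_table <- function(df, path) {
  validate_study_table(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cohort eligibility filter
#'
#' Applies the study's inclusion/exclusion rules to a screened table.
#' Inclusion requires a hemorrhagic-stroke etiology, an Ashworth score
#' of at most `max_ashworth` and at most `max_months` since the
#' incident; records with neurological comorbidities affecting hand
#' motion (e.g. Parkinson's disease) or musculoskeletal deficits
#' limiting finger range of motion (arthritis, joint stiffness) are
#' excluded. A record matching several exclusion reasons is tallied
#' under the first in the fixed precedence: neurological comorbidity,
#' arthritis, joint stiffness, Ashworth, time since incident, etiology.
#'
#' @param records A study table (see [validate_study_table()]; the
#'   questionnaire columns may be absent at screening time).
#' @param criteria List overriding `max_ashworth` (default 3),
#'   `max_months` (6), `etiology` (`"hemorrhagic stroke"`), and the
#'   regular expressions `neuro_pattern`, `arthritis_pattern`,
#'   `stiffness_pattern` matched (case-insensitively) against the
#'   comorbidity labels.
#' @return List with `included` (the eligible rows) and `tally` (named
#'   integer vector of exclusions by reason; reasons with zero count
#'   omitted). `nrow(included) + sum(tally) == nrow(records)` always.
#' @export
cohort_filter <- function(records, criteria = list()) {
  cr <- utils::modifyList(
    list(max_ashworth = 3, max_months = 6, etiology = "hemorrhagic stroke",
         neuro_pattern = "parkinson", arthritis_pattern = "arthritis",
         stiffness_pattern = "stiffness"),
    criteria)
  for (f in c("ashworth", "months_since_diagnosis", "etiology", "comorbidity"))
    if (is.null(records[[f]]))
      stop("records are missing required field: ", f)
  reason_of <- function(i) {
    com <- tolower(records$comorbidity[i])
    if (grepl(cr$neuro_pattern, com)) return("neurological_comorbidity")
    if (grepl(cr$arthritis_pattern, com)) return("arthritis")
    if (grepl(cr$stiffness_pattern, com)) return("joint_stiffness")
    if (records$ashworth[i] > cr$max_ashworth) return("ashworth")
    if (records$months_since_diagnosis[i] > cr$max_months)
      return("time_since_incident")
    if (tolower(records$etiology[i]) != tolower(cr$etiology))
      return("etiology")
    NA_character_
  }
  reasons <- if (nrow(records) == 0) character(0)
             else vapply(seq_len(nrow(records)), reason_of, character(1))
  included <- records[is.na(reasons), , drop = FALSE]
  tally_tab <- table(reasons[!is.na(reasons)])
  tally <- stats::setNames(as.integer(tally_tab), names(tally_tab))
  list(included = included, tally = tally)
}

# round half away from zero at `digits` decimals (printed-table style,
# unlike R's round-half-even)
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize the 4-level questionnaire
#'
#' Per item: the percentage of respondents in each category and the
#' collapsed agree (agree + strongly agree) and disagree (disagree +
#' strongly disagree) percentages, rounded to one decimal place, half
#' away from zero — the precision clinical tables print.
#'
#' @param responses Either a study table data.frame (items read from the
#'   `q*` columns) or an items x 4 count matrix with columns named by
#'   the response levels.
#' @param n Number of respondents; inferred from raw responses, required
#'   (as row sums consistency check) for count input.
#' @return Data.frame, one row per item: per-category percentages plus
#'   `agree_pct` and `disagree_pct`.
#' @export
likert_summarize <- function(responses, n = NULL) {
  if (is.matrix(responses)) {
    counts <- responses[, LIKERT_LEVELS, drop = FALSE]
    if (is.null(n)) n <- max(rowSums(counts))
    if (any(rowSums(counts) > n)) stop("category counts exceed n")
    items <- rownames(counts)
    if (is.null(items)) items <- paste0("q", seq_len(nrow(counts)))
  } else {
    cols <- intersect(likert_cols(), names(responses))
    if (length(cols) == 0) stop("no questionnaire columns found")
    n <- nrow(responses)
    counts <- t(vapply(cols, function(q)
      table(factor(responses[[q]], levels = LIKERT_LEVELS)),
      integer(length(LIKERT_LEVELS))))
    colnames(counts) <- LIKERT_LEVELS
    items <- cols
  }
  pct <- round_half_away(100 * counts / n, 1)
  data.frame(item = items,
             strongly_disagree_pct = pct[, "strongly_disagree"],
             disagree_pct_only = pct[, "disagree"],
             agree_pct_only = pct[, "agree"],
             strongly_agree_pct = pct[, "strongly_agree"],
             agree_pct = round_half_away(
               100 * (counts[, "agree"] + counts[, "strongly_agree"]) / n, 1),
             disagree_pct = round_half_away(
               100 * (counts[, "disagree"] + counts[, "strongly_disagree"]) / n, 1),
             row.names = NULL)
}

#' Generate synthetic paired scores from a bivariate normal
#'
#' Stand-in for the study's unreleased per-patient scores: draws `n`
#' pairs with the requested means, SDs and correlation; optionally
#' rounds to the nearest non-negative integer (scores are block counts).
#' Deterministic per seed and leaves the caller's RNG untouched.
#'
#' @param n Number of pairs.
#' @param mean_x,sd_x,mean_y,sd_y Moments of the two margins.
#' @param rho Correlation, `|rho| < 1`.
#' @param seed Integer seed.
#' @param integerize Round to nearest non-negative integer block counts?
#' @return Data.frame with columns `x` and `y`.
#' @export
generate_paired_scores <- function(n, mean_x, sd_x, mean_y, sd_y, rho,
                                   seed = 1, integerize = FALSE) {
  stopifnot(n >= 1, sd_x > 0, sd_y > 0, abs(rho) < 1)
  sigma <- matrix(c(sd_x^2, rho * sd_x * sd_y,
                    rho * sd_x * sd_y, sd_y^2), 2)
  rng <- rng_stream(seed)
  m <- with_rng_stream(rng,
    MASS::mvrnorm(n, mu = c(mean_x, mean_y), Sigma = sigma))
  m <- matrix(m, ncol = 2)
  if (integerize) m <- pmax(round(m), 0)
  data.frame(x = m[, 1], y = m[, 2])
}

#' Synthetic post-inclusion study table
#'
#' Builds a full synthetic study table shaped like the validation
#' cohort: `n` hemorrhagic-stroke patients with paired BBT / AR-BBT
#' scores drawn from a bivariate normal with the cohort's reported
#' moments (BBT 36.64 +/- 6.14, AR-BBT 11.90 +/- 2.11, r = 0.918),
#' demographics near the cohort means, Ashworth scores within the
#' inclusion range and 11 questionnaire responses.
#'
#' @param n Patients (default 31).
#' @param seed Integer seed.
#' @param bbt_mean,bbt_sd,arbbt_mean,arbbt_sd,rho Score-generating
#'   moments.
#' @return A validated study table data.frame.
#' @export
synthetic_study_table <- function(n = 31, seed = 1,
                                  bbt_mean = 36.64, bbt_sd = 6.14,
                                  arbbt_mean = 11.90, arbbt_sd = 2.11,
                                  rho = 0.918) {
  scores <- generate_paired_scores(n, bbt_mean, bbt_sd, arbbt_mean, arbbt_sd,
                                   rho, seed = derive_seed(seed, 1),
                                   integerize = TRUE)
  rng <- rng_stream(derive_seed(seed, 2))
  demo <- with_rng_stream(rng, {
    list(age = round(stats::rnorm(n, 72.22, 5.23), 1),
         sex = sample(c("male", "female"), n, replace = TRUE,
                      prob = c(20, 11) / 31),
         months = round(pmin(pmax(stats::rnorm(n, 4.49, 1.12), 0.5), 6), 1),
         ashworth = sample(0:3, n, replace = TRUE, prob = c(1, 4, 5, 3)),
         q = matrix(sample(LIKERT_LEVELS, n * N_LIKERT_ITEMS, replace = TRUE,
                           prob = c(0.25, 0.25, 0.3, 0.2)),
                    nrow = n))
  })
  df <- data.frame(patient_id = sprintf("P%02d", seq_len(n)),
                   bbt_score = as.integer(scores$x),
                   arbbt_score = as.integer(scores$y),
                   age = demo$age, sex = demo$sex,
                   months_since_diagnosis = demo$months,
                   ashworth = demo$ashworth,
                   etiology = "hemorrhagic stroke",
                   comorbidity = "")
  q <- as.data.frame(demo$q)
  names(q) <- likert_cols()
  df <- cbind(df, q)
  validate_study_table(df)
  df
}

#' Synthetic screened cohort (48 records)
#'
#' A screening-stage table shaped like the study's recruitment: 31
#' eligible hemorrhagic-stroke patients plus 5 with Parkinson's disease
#' comorbidity, 9 with rheumatoid arthritis of the finger joints and 3
#' with finger-joint stiffness, in shuffled order. Running
#' [cohort_filter()] on it reproduces the 48 -> 31 eligibility funnel.
#'
#' @param seed Integer seed.
#' @return A data.frame of 48 screening records (no questionnaire
#'   columns).
#' @export
synthetic_screened_cohort <- function(seed = 1) {
  base <- synthetic_study_table(31, seed = derive_seed(seed, 10))
  base <- base[, setdiff(names(base), likert_cols())]
  extra_labels <- c(rep("Parkinson's disease", 5),
                    rep("rheumatoid arthritis (finger joints)", 9),
                    rep("finger joint stiffness / reduced ROM", 3))
  rng <- rng_stream(derive_seed(seed, 11))
  extra <- with_rng_stream(rng, {
    k <- length(extra_labels)
    data.frame(patient_id = sprintf("S%02d", seq_len(k)),
               bbt_score = sample(20:45, k, replace = TRUE),
               arbbt_score = sample(5:16, k, replace = TRUE),
               age = round(stats::rnorm(k, 72, 5), 1),
               sex = sample(c("male", "female"), k, replace = TRUE),
               months_since_diagnosis = round(stats::runif(k, 1, 6), 1),
               ashworth = sample(0:3, k, replace = TRUE),
               etiology = "hemorrhagic stroke",
               comorbidity = extra_labels)
  })
  out <- rbind(base, extra)
  perm <- with_rng_stream(rng, sample(nrow(out)))
  out[perm, , drop = FALSE]
}
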