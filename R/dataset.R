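#' Tasting-vs-rinse feature normalization
#'
#' Element-wise relative change of the tasting-epoch EEG feature vector with
#' respect to the same trial's water-rinse vector: `(x - y) / y`. Applied to
#' the 304 EEG-derived entries only (demographics are appended afterwards).
#'
#' @param x_tl Tasting-epoch feature vector.
#' @param y_wr Water-rinse feature vector of the same trial (equal length).
#' @param eps Guard: any `|y_wr| < eps` is an error (default 1e-12).
#' @return Normalized vector of the same length and names.
#' @export
#' @examples
#' wr_normalize(c(2, 3, 4), c(1, 2, 4))  # 1.0 0.5 0.0
wr_normalize <- function(x_tl, y_wr, eps = 1e-12) {
  if (length(x_tl) != length(y_wr))
    stop("tasting and rinse feature vectors must have equal length")
  bad <- which(abs(y_wr) < eps)
  if (length(bad))
    stop(sprintf("rinse features too close to zero at indices: %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  (x_tl - y_wr) / y_wr
}

#' Log-transform sensory ratings
#'
#' Ratings on the 0-10 ratio scale are modeled as `log(1 + y)`;
#' [invert_targets()] is the exact inverse `exp(t) - 1`.
#'
#' @param y Ratings in `[0, 10]`.
#' @return Transformed targets.
#' @export
transform_targets <- function(y) {
  if (any(y < 0)) stop("ratings must be nonnegative")
  log1p(y)
}

#' @rdname transform_targets
#' @param t Transformed targets.
#' @export
invert_targets <- function(t) expm1(t)

#' Extract per-trial normalized EEG features of one session
#'
#' Estimates the subject's IAF from the baseline, derives the IAF-anchored
#' bands, computes the 304-long spectral+temporal feature vector of every
#' tasting (TL) and rinse (WR) epoch, and applies [wr_normalize()] per trial.
#'
#' @param session A `session_recording`.
#' @return List with `iaf`, and `records`: data.frame of one row per
#'   (phase, trial) holding subject_id, phase, trial and the 304 normalized
#'   features.
#' @export
extract_session_features <- function(session) {
  iaf <- estimate_iaf(session$baseline)
  bands <- define_bands(iaf)
  rows <- list()
  for (phase in names(session$trials)) {
    for (tr in seq_along(session$trials[[phase]])) {
      pair <- session$trials[[phase]][[tr]]
      x_tl <- extract_epoch_features(pair$tl, bands)
      y_wr <- extract_epoch_features(pair$wr, bands)
      xp <- wr_normalize(x_tl, y_wr)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = session$subject_id, phase = phase, trial = tr,
        t(xp), check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  list(iaf = iaf, records = do.call(rbind, rows))
}

#' A trial-by-feature table with targets
#'
#' @param meta data.frame with subject_id, phase, trial (one row per tasting
#'   trial).
#' @param X Numeric feature matrix (rows aligned with `meta`), 306 columns:
#'   190 spectral + 114 temporal + age + group.
#' @param y Numeric target matrix (rows aligned, one column per attribute),
#'   already log(1+rating)-transformed.
#' @param tag Dataset tag: `"Be"`, `"Co"` or `"BeCo"`.
#' @return A `feature_table`.
#' @export
feature_table <- function(meta, X, y, tag) {
  stopifnot(nrow(meta) == nrow(X), nrow(X) == nrow(y))
  if (anyNA(X)) stop("feature matrix contains NA")
  structure(list(meta = meta, X = X, y = y, tag = tag), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table:%s> %d trials x %d features, targets: %s\n",
              x$tag, nrow(x$X), ncol(x$X), paste(colnames(x$y), collapse = ", ")))
  invisible(x)
}

#' Assemble a per-phase dataset from extracted features
#'
#' One row per tasting trial: the 304 rinse-normalized EEG features, then age
#' and group (encoded 0 = T, 1 = E) appended after normalization (applying
#' the rinse normalization to demographics would always yield zero). Targets
#' are the log(1+rating)-transformed attribute ratings. `tag = "BeCo"`
#' row-concatenates the two phases.
#'
#' @param records data.frame of normalized feature records (rbind of
#'   [extract_session_features()] `records`).
#' @param ratings data.frame subject_id, phase, trial, attribute, rating.
#' @param demographics data.frame subject_id, age, group.
#' @param tag `"Be"`, `"Co"` or `"BeCo"`.
#' @param attributes Attribute order for the target columns.
#' @return A [feature_table()].
#' @export
assemble_dataset <- function(records, ratings, demographics, tag,
                             attributes = c("bitter", "sweet", "acid", "astringent")) {
  stopifnot(tag %in% c("Be", "Co", "BeCo"))
  phases <- if (tag == "BeCo") c("Be", "Co") else tag
  rec <- records[records$phase %in% phases, , drop = FALSE]
  rec <- rec[order(match(rec$phase, phases), rec$subject_id, rec$trial), , drop = FALSE]
  # completeness: every subject must contribute every (phase, trial)
  for (sid in unique(demographics$subject_id)) for (ph in phases) {
    have <- rec$trial[rec$subject_id == sid & rec$phase == ph]
    miss <- setdiff(1:4, have)
    if (length(miss))
      stop(sprintf("missing trial: subject %s, phase %s, trial %s",
                   sid, ph, paste(miss, collapse = ",")))
  }
  meta <- rec[, c("subject_id", "phase", "trial")]
  rownames(meta) <- NULL
  eeg <- as.matrix(rec[, setdiff(colnames(rec), c("subject_id", "phase", "trial"))])
  di <- match(meta$subject_id, demographics$subject_id)
  if (anyNA(di)) stop("feature rows reference subjects absent from demographics")
  X <- cbind(eeg,
             age = demographics$age[di],
             group = as.numeric(demographics$group[di] == "E"))
  y <- sapply(attributes, function(a) {
    key <- paste(meta$subject_id, meta$phase, meta$trial)
    r <- ratings[ratings$attribute == a, ]
    ri <- match(key, paste(r$subject_id, r$phase, r$trial))
    if (anyNA(ri)) stop(sprintf("missing ratings for attribute '%s'", a))
    transform_targets(r$rating[ri])
  })
  feature_table(meta, X, y, tag)
}

#' Subject-wise feature standardization
#'
#' Applied per subject and per feature column, so no information crosses
#' subjects (leave-one-subject-out safe by construction). Methods:
#' \describe{
#'   \item{zscore}{center by the subject mean, scale by the subject SD.}
#'   \item{minmax}{map the subject range to \[0, 1\].}
#'   \item{median}{robust z-score (center by median, scale by IQR/1.349),
#'     then logistic squashing to (0, 1).}
#'   \item{none}{identity.}
#' }
#' A zero subject-level scale leaves the feature centered only (one warning
#' summarizes all such features). The categorical `group` column is never
#' standardized.
#'
#' @param table A [feature_table()].
#' @param method One of `"zscore"`, `"minmax"`, `"median"`, `"none"`.
#' @return A [feature_table()] of identical shape.
#' @export
standardize_features <- function(table, method = c("zscore", "minmax", "median", "none")) {
  method <- match.arg(method)
  if (method == "none") return(table)
  X <- table$X
  skip <- which(colnames(X) == "group")
  cols <- setdiff(seq_len(ncol(X)), skip)
  n_degenerate <- 0L
  for (sid in unique(table$meta$subject_id)) {
    rows <- which(table$meta$subject_id == sid)
    if (length(rows) < 2)
      stop(sprintf("subject %s has fewer than 2 rows: cannot estimate a scale", sid))
    sub <- X[rows, cols, drop = FALSE]
    if (method == "zscore") {
      ctr <- colMeans(sub)
      scl <- apply(sub, 2, stats::sd)
    } else if (method == "minmax") {
      ctr <- apply(sub, 2, min)
      scl <- apply(sub, 2, max) - ctr
    } else {                                        # median
      ctr <- apply(sub, 2, stats::median)
      scl <- apply(sub, 2, stats::IQR) / 1.349
    }
    zero <- scl <= 0
    n_degenerate <- n_degenerate + sum(zero)
    scl[zero] <- 1                                  # centered only
    z <- sweep(sweep(sub, 2, ctr), 2, scl, "/")
    if (method == "median") z <- 1 / (1 + exp(-z))  # logistic squash
    X[rows, cols] <- z
  }
  if (n_degenerate > 0)
    warning(sprintf("%d subject-level feature scales were zero; those features were centered only",
                    n_degenerate))
  feature_table(table$meta, X, table$y, table$tag)
}

#' Restrict a feature table to a set of subjects
#' @param table A [feature_table()].
#' @param subjects Character vector of subject ids to keep.
#' @return A [feature_table()] with the matching rows.
#' @export
subset_subjects <- function(table, subjects) {
  rows <- table$meta$subject_id %in% subjects
  feature_table(table$meta[rows, , drop = FALSE],
                table$X[rows, , drop = FALSE],
                table$y[rows, , drop = FALSE], table$tag)
}

#' Write / read a feature table as CSV plus a JSON manifest
#'
#' The CSV holds one header row and one row per tasting trial: subject_id,
#' phase, trial, the 306 feature columns (systematic names such as
#' `C3.p_alpha`, `Pz.hjorth_C`, `age`, `group`) and one `y_<attribute>`
#' column per transformed target. The manifest records the dataset tag and
#' the target transform.
#'
#' @param table A [feature_table()].
#' @param path Output stem; writes `<path>.csv` and `<path>.json`.
#' @return Invisibly, the paths written.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$y
  colnames(y) <- paste0("y_", colnames(y))
  df <- cbind(table$meta, as.data.frame(table$X, check.names = FALSE),
              as.data.frame(y))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(tag = table$tag,
                            n_features = ncol(table$X),
                            targets = colnames(table$y),
                            target_transform = "log1p"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(paste0(path, c(".csv", ".json")))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  manifest <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
  ycols <- paste0("y_", manifest$targets)
  meta <- df[, c("subject_id", "phase", "trial")]
  X <- as.matrix(df[, setdiff(colnames(df), c(colnames(meta), ycols))])
  y <- as.matrix(df[, ycols])
  colnames(y) <- manifest$targets
  if (ncol(X) != manifest$n_features)
    stop(sprintf("feature count mismatch: manifest says %d, CSV has %d",
                 manifest$n_features, ncol(X)))
  feature_table(meta, X, y, manifest$tag)
}

#' Simulate a panel and build the three datasets
#'
#' End-to-end data stage: generates the panel, simulates each subject's
#' session, extracts rinse-normalized features (dropping raw epochs as it
#' goes, to bound memory), and assembles the Be, Co and BeCo feature tables.
#'
#' @param config A [panel_config()].
#' @param progress Log per-subject progress messages (default FALSE).
#' @return List with `panel`, `demographics`, `ratings`, `records`,
#'   `iaf_estimates` (data.frame subject_id, true_iaf, estimated_iaf) and
#'   `tables` (list Be/Co/BeCo of [feature_table()]s).
#' @export
build_panel_datasets <- function(config, progress = FALSE) {
  panel <- generate_panel(config)
  demographics <- panel_demographics(panel)
  all_records <- list()
  all_ratings <- list()
  iaf <- list()
  for (s in panel) {
    if (progress) log_stage("extracting features: subject %s", s$subject_id)
    session <- simulate_session(s, config)
    fx <- extract_session_features(session)
    all_records[[s$subject_id]] <- fx$records
    all_ratings[[s$subject_id]] <- session$ratings
    iaf[[s$subject_id]] <- data.frame(subject_id = s$subject_id,
                                      true_iaf = s$true_iaf,
                                      estimated_iaf = fx$iaf)
  }
  records <- do.call(rbind, all_records)
  ratings <- do.call(rbind, all_ratings)
  rownames(records) <- rownames(ratings) <- NULL
  tables <- lapply(stats::setNames(c("Be", "Co", "BeCo"), c("Be", "Co", "BeCo")),
                   function(tag) assemble_dataset(records, ratings, demographics,
                                                  tag, config$attributes))
  list(panel = panel, demographics = demographics, ratings = ratings,
       records = records,
       iaf_estimates = do.call(rbind, c(iaf, list(make.row.names = FALSE))),
       tables = tables)
}
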