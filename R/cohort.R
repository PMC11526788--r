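#' Load a patient/slide/label manifest
#'
#' Validates a manifest with columns `patient_id`, `slide_id`, `label`
#' (levels `PV` and `WT`). All slides of a patient must carry the same label;
#' discordant labels are rejected.
#'
#' @param manifest A `data.frame` or path to a CSV file.
#' @return The validated manifest with `label` as a factor `c("WT", "PV")`.
#' @export
read_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("patient_id", "slide_id", "label")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(manifest$label %in% c("PV", "WT")))
    stop("labels must be 'PV' or 'WT'", call. = FALSE)
  if (anyDuplicated(manifest$slide_id))
    stop("duplicate slide_id in manifest", call. = FALSE)
  per_pat <- tapply(manifest$label, manifest$patient_id,
                    function(x) length(unique(x)))
  if (any(per_pat > 1L))
    stop("discordant labels within patient(s): ",
         paste(names(per_pat)[per_pat > 1L], collapse = ", "), call. = FALSE)
  manifest$label <- factor(manifest$label, levels = c("WT", "PV"))
  manifest
}

patient_table <- function(manifest) {
  pat <- unique(manifest[, c("patient_id", "label")])
  pat[order(pat$patient_id), , drop = FALSE]
}

#' Stratified train/test split at the patient level
#'
#' Splits patients (never individual slides) into train and test sets,
#' stratified by label: per class, `round(train_frac * class size)` patients
#' go to training. Because assignment is at patient granularity, all slides
#' of a patient land in the same partition by construction, preventing
#' leakage between train and test.
#'
#' @param manifest Manifest as from [read_manifest()].
#' @param train_frac Fraction of each class assigned to training. Default 0.8.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `patient_id`, `label`, `partition`
#'   (`"train"`/`"test"`), and attribute `seed`.
#' @export
stratified_patient_split <- function(manifest, train_frac = 0.8, seed = 1L) {
  manifest <- read_manifest(manifest)
  pat <- patient_table(manifest)
  if (train_frac < 0 || train_frac > 1)
    stop("`train_frac` must be in [0, 1]", call. = FALSE)
  if (any(table(pat$label) == 0L))
    stop("need at least one patient per class", call. = FALSE)
  out <- with_seed_(seed, {
    parts <- lapply(split(pat, pat$label), function(cls) {
      if (nrow(cls) == 0L) return(cls[0, ])
      n_train <- round(train_frac * nrow(cls))
      if (train_frac < 1 && train_frac > 0 &&
          (n_train == 0L || n_train == nrow(cls)) && nrow(cls) < 2L)
        stop("stratification-infeasible: class ", cls$label[1],
             " has too few patients", call. = FALSE)
      idx <- sample.int(nrow(cls))
      cls$partition <- "test"
      cls$partition[idx[seq_len(n_train)]] <- "train"
      cls
    })
    do.call(rbind, parts)
  })
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Class-balanced k-fold split at the patient level
#'
#' Assigns each patient to exactly one of `k` folds, dealing the shuffled
#' patients of each class round-robin so folds are class-balanced to within
#' one patient.
#'
#' @param manifest Manifest as from [read_manifest()].
#' @param k Number of folds. Default 5.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `patient_id`, `label`, `fold`
#'   (0-based), and attribute `seed`.
#' @export
kfold_patient_split <- function(manifest, k = 5L, seed = 1L) {
  manifest <- read_manifest(manifest)
  pat <- patient_table(manifest)
  counts <- table(pat$label)
  if (k > 1L && any(counts < k))
    stop("infeasible: a class has fewer than k patients", call. = FALSE)
  out <- with_seed_(seed, {
    parts <- lapply(split(pat, pat$label), function(cls) {
      idx <- sample.int(nrow(cls))
      cls$fold <- ((seq_len(nrow(cls)) - 1L) %% k)[order(idx)]
      cls
    })
    do.call(rbind, parts)
  })
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Group tile features into fixed-size bags
#'
#' Shuffles the `M` tile feature rows of one slide with a seeded RNG and
#' partitions them into `floor(M / N)` disjoint bags of exactly `N`
#' instances. The remainder is dropped (default) or one extra bag is padded
#' by resampling the remainder with replacement (`remainder_policy = "pad"`).
#'
#' @param features `M x D` numeric matrix of per-tile features for one slide.
#' @param N Bag size (instances per bag). Default 35.
#' @param seed Integer seed for the shuffle.
#' @param slide_id,patient_id,label Metadata copied into every bag.
#' @param remainder_policy `"drop"` (default) or `"pad"`.
#' @return A list of `bag` objects: each a list with `bag_id`, `slide_id`,
#'   `patient_id`, `label`, `features` (`N x D`), `tile_idx` (row indices of
#'   `features` used). Empty list (with a warning) when `M < N` under drop.
#' @export
make_bags <- function(features, N = 35L, seed = 1L, slide_id = "slide",
                      patient_id = "patient", label = NA_character_,
                      remainder_policy = c("drop", "pad")) {
  remainder_policy <- match.arg(remainder_policy)
  features <- as.matrix(features)
  m <- nrow(features)
  if (m < 1L) stop("no tile features supplied", call. = FALSE)
  n_full <- floor(m / N)
  if (n_full == 0L && remainder_policy == "drop") {
    warning("fewer tiles (", m, ") than bag size (", N, "); no bags formed")
    return(list())
  }
  with_seed_(seed, {
    perm <- sample.int(m)
    chunks <- if (n_full > 0L)
      split(perm[seq_len(n_full * N)], rep(seq_len(n_full), each = N))
    else list()
    if (remainder_policy == "pad" && n_full * N < m) {
      rest <- perm[(n_full * N + 1L):m]
      pad <- sample(rest, N - length(rest), replace = TRUE)
      chunks <- c(chunks, list(c(rest, pad)))
    }
    lapply(seq_along(chunks), function(i) {
      idx <- chunks[[i]]
      structure(list(bag_id = sprintf("%s_bag%03d", slide_id, i),
                     slide_id = slide_id, patient_id = patient_id,
                     label = label,
                     features = features[idx, , drop = FALSE],
                     tile_idx = idx),
                class = "bag")
    })
  })
}

#' @export
print.bag <- function(x, ...) {
  cat(sprintf("<bag %s: %d x %d features, slide %s, label %s>\n",
              x$bag_id, nrow(x$features), ncol(x$features), x$slide_id,
              as.character(x$label)))
  invisible(x)
}
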