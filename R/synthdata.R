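# Seeded synthetic-data generators with known ground truth. They emulate the
# shapes of the real inputs -- slides as stained blobs on a white canvas,
# bags of features in which only a few "witness" instances carry the
# bag-level signal, and QuPath-style cell-measurement tables with group
# shifts -- so every pipeline stage is testable without any image downloads.

#' Generate a synthetic slide image with a known tumor mask
#'
#' Draws colored elliptical blobs ("tumor" and "stroma") on a white canvas.
#' The returned mask marks tumor-blob pixels, giving downstream tile
#' classification an exact ground truth.
#'
#' @param width,height Canvas size in pixels.
#' @param n_tumor_blobs,n_stroma_blobs Blob counts.
#' @param blob_radius Two-vector: min/max blob semi-axis in pixels.
#' @param tumor_color,stroma_color RGB triples (0--255); defaults are a
#'   hematoxylin-like purple and an eosin-like pink.
#' @param seed Integer seed; the same seed gives an identical image.
#' @return List with `image` (H x W x 3, 0--255), `tumor_mask` (H x W
#'   logical), and `blobs` (`data.frame` registry: cx, cy, rx, ry, type).
#' @export
make_synthetic_slide <- function(width = 1536L, height = 1536L,
                                 n_tumor_blobs = 3L, n_stroma_blobs = 3L,
                                 blob_radius = c(120, 260),
                                 tumor_color = c(120, 60, 140),
                                 stroma_color = c(235, 170, 190),
                                 seed = 1L) {
  if (width < 1 || height < 1) stop("invalid-spec: empty canvas",
                                    call. = FALSE)
  if (2 * max(blob_radius) > min(width, height))
    stop("invalid-spec: blob cannot fit inside the canvas", call. = FALSE)
  img <- array(255, c(height, width, 3))
  mask <- matrix(FALSE, height, width)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), times = width), height, width)
  n_total <- n_tumor_blobs + n_stroma_blobs
  blobs <- with_seed_(seed, {
    if (n_total == 0L) {
      data.frame(cx = numeric(), cy = numeric(), rx = numeric(),
                 ry = numeric(), type = character())
    } else {
      rx <- stats::runif(n_total, blob_radius[1], blob_radius[2])
      ry <- stats::runif(n_total, blob_radius[1], blob_radius[2])
      data.frame(
        cx = stats::runif(n_total, rx + 1, width - rx),
        cy = stats::runif(n_total, ry + 1, height - ry),
        rx = rx, ry = ry,
        type = c(rep("tumor", n_tumor_blobs),
                 rep("stroma", n_stroma_blobs)))
    }
  })
  for (i in seq_len(nrow(blobs))) {
    b <- blobs[i, ]
    inside <- ((xs - b$cx) / b$rx)^2 + ((ys - b$cy) / b$ry)^2 <= 1
    col <- if (b$type == "tumor") tumor_color else stroma_color
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- col[ch]
      img[, , ch] <- plane
    }
    if (b$type == "tumor") mask <- mask | inside
  }
  list(image = img, tumor_mask = mask, blobs = blobs)
}

#' Generate a synthetic MIL benchmark with planted witness instances
#'
#' Background instances are drawn from an isotropic Gaussian
#' `N(0, noise_sd^2 I)`. In each positive bag, `round(witness_rate * N)`
#' instances are additionally shifted by `shift` along one fixed seeded unit
#' direction; negative bags contain no witnesses. The exact witness
#' positions are recorded, so attention-recovery can be scored against
#' ground truth. Defaults are the package's standard CPU-scale benchmark:
#' 200 training and 100 test bags of 10 instances in 32 dimensions with a
#' 0.2 witness rate and a shift of 2 at unit noise.
#'
#' @param n_bags_pos,n_bags_neg Bag counts per class.
#' @param N Instances per bag.
#' @param D Feature dimensionality.
#' @param witness_rate Fraction of witness instances in positive bags.
#' @param shift Mean offset of witnesses along the signal direction.
#' @param noise_sd Background standard deviation.
#' @param seed Integer seed; same seed, byte-identical arrays.
#' @param direction Optional unit D-vector: the witness shift direction.
#'   Default `NULL` draws a seeded random direction. Pass the same vector to
#'   generate train and test sets that share one signal.
#' @return List with `bags` (list of `bag` objects; labels `PV` for
#'   positive, `WT` for negative), `witness` (list of logical N-vectors),
#'   and `direction` (the unit signal direction).
#' @export
make_synthetic_bags <- function(n_bags_pos = 100L, n_bags_neg = 100L,
                                N = 10L, D = 32L, witness_rate = 0.2,
                                shift = 2.0, noise_sd = 1.0, seed = 1L,
                                direction = NULL) {
  if (witness_rate <= 0 || witness_rate > 1)
    stop("witness_rate must lie in (0, 1]", call. = FALSE)
  n_wit <- max(1L, round(witness_rate * N))
  if (!is.null(direction)) {
    stopifnot(length(direction) == D)
    direction <- direction / sqrt(sum(direction^2))
  }
  with_seed_(seed, {
    u <- if (is.null(direction)) {
      u0 <- stats::rnorm(D)
      u0 / sqrt(sum(u0^2))
    } else direction
    total <- n_bags_pos + n_bags_neg
    labels <- c(rep("PV", n_bags_pos), rep("WT", n_bags_neg))
    bags <- vector("list", total)
    witness <- vector("list", total)
    for (i in seq_len(total)) {
      x <- matrix(stats::rnorm(N * D, sd = noise_sd), N, D)
      wmask <- rep(FALSE, N)
      if (labels[i] == "PV") {
        wmask[sample.int(N, n_wit)] <- TRUE
        x[wmask, ] <- x[wmask, , drop = FALSE] +
          matrix(shift * u, sum(wmask), D, byrow = TRUE)
      }
      bags[[i]] <- structure(
        list(bag_id = sprintf("synth_bag%04d", i),
             slide_id = sprintf("synth_slide%04d", i),
             patient_id = sprintf("synth_pat%04d", i),
             label = labels[i], features = x, tile_idx = seq_len(N)),
        class = "bag")
      witness[[i]] <- wmask
    }
    list(bags = bags, witness = witness, direction = u)
  })
}

#' Generate a synthetic cell-measurement table with group effects
#'
#' Emulates a QuPath-style measurement export: log-normal cell and nucleus
#' areas with `nucleus_area < cell_area` enforced by construction (the
#' nucleus-to-cell ratio is drawn in (0, 1)), cell classes `tumor` / `TIL` /
#' `stroma` in stated proportions, and a `group` column (`PV` / `WT`) where
#' the PV group's stated features are shifted additively on the log scale.
#'
#' @param n_per_group Cells per group.
#' @param effect Named numeric vector of additive log-scale shifts applied
#'   to the PV group, e.g. `c(cell_area = 0.1)`. Unknown names are an error.
#'   Shifting `cell_area` shifts the nucleus proportionally (the ratio is
#'   sampled independently); shifting `nucleus_to_cell_ratio` acts on the
#'   logit of the ratio.
#' @param class_proportions Mixture over `tumor`, `TIL`, `stroma`.
#' @param meanlog_area,sdlog_area Log-normal parameters of `cell_area`
#'   (roughly QuPath-scale square-micron areas).
#' @param seed Integer seed.
#' @return `data.frame` with columns `cell_id`, `group`, `cell_class`,
#'   `cell_area`, `nucleus_area`, `nucleus_to_cell_ratio`, `eccentricity`,
#'   `stain_od`.
#' @export
make_cell_table <- function(n_per_group = 1000L,
                            effect = c(cell_area = 0),
                            class_proportions = c(tumor = 0.6, TIL = 0.2,
                                                  stroma = 0.2),
                            meanlog_area = log(450), sdlog_area = 0.35,
                            seed = 1L) {
  known <- c("cell_area", "nucleus_to_cell_ratio", "eccentricity",
             "stain_od")
  if (length(effect) && !all(names(effect) %in% known))
    stop("unknown effect feature(s): ",
         paste(setdiff(names(effect), known), collapse = ", "),
         call. = FALSE)
  eff <- function(nm) if (nm %in% names(effect)) effect[[nm]] else 0
  with_seed_(seed, {
    one_group <- function(group, shifted) {
      s <- function(nm) if (shifted) eff(nm) else 0
      cell_area <- stats::rlnorm(n_per_group,
                                 meanlog_area + s("cell_area"), sdlog_area)
      ratio <- stats::plogis(stats::rnorm(n_per_group, -0.6, 0.4) +
                               s("nucleus_to_cell_ratio"))
      ecc <- stats::plogis(stats::rnorm(n_per_group, 0.4, 0.5) +
                             s("eccentricity"))
      od <- stats::rlnorm(n_per_group, log(0.8) + s("stain_od"), 0.3)
      data.frame(
        group = group,
        cell_class = sample(names(class_proportions), n_per_group,
                            replace = TRUE, prob = class_proportions),
        cell_area = cell_area,
        nucleus_area = cell_area * ratio,
        nucleus_to_cell_ratio = ratio,
        eccentricity = ecc,
        stain_od = od,
        stringsAsFactors = FALSE)
    }
    out <- rbind(one_group("WT", FALSE), one_group("PV", TRUE))
    out$cell_id <- sprintf("cell%05d", seq_len(nrow(out)))
    out[, c("cell_id", "group", "cell_class", "cell_area", "nucleus_area",
            "nucleus_to_cell_ratio", "eccentricity", "stain_od")]
  })
}

#' Generate a synthetic two-stain image from a known basis
#'
#' Builds optical density as `OD = S C` with the given unit-norm stain
#' vectors and sparse random concentrations (each pixel expresses mostly one
#' stain), then converts to RGB. Used to validate stain-basis recovery.
#'
#' @param stain_vectors 3 x 2 matrix of unit-norm non-negative OD columns;
#'   default is a standard hematoxylin/eosin pair.
#' @param width,height Image size.
#' @param max_conc Upper bound of the dominant-stain concentration.
#' @param seed Integer seed.
#' @return List with `image` (H x W x 3, 0--255), `stain_vectors`, and
#'   `concentrations` (2 x n_pixels).
#' @export
make_synthetic_stain_image <- function(stain_vectors = NULL, width = 64L,
                                       height = 64L, max_conc = 1.5,
                                       seed = 1L) {
  if (is.null(stain_vectors)) {
    stain_vectors <- cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
    stain_vectors <- sweep(stain_vectors, 2L,
                           sqrt(colSums(stain_vectors^2)), "/")
  }
  npix <- width * height
  conc <- with_seed_(seed, {
    dominant <- sample(1:2, npix, replace = TRUE)
    major <- stats::runif(npix, 0.4 * max_conc, max_conc)
    minor <- stats::runif(npix, 0, 0.05 * max_conc)
    rbind(ifelse(dominant == 1, major, minor),
          ifelse(dominant == 2, major, minor))
  })
  od <- stain_vectors %*% conc
  img <- array(0, c(height, width, 3))
  for (ch in 1:3) img[, , ch] <- matrix(od_to_rgb(od[ch, ]), height, width)
  list(image = img, stain_vectors = stain_vectors, concentrations = conc)
}
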