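# Synthetic stimulus world with the latent-factor structure of 3dshapes:
# six independent generative factors, of which object color, scale and shape
# define a 64-way object class; floor color, wall color and orientation are
# class-irrelevant nuisance factors.

#' Number of values per latent factor
#'
#' The six generative factors and how many values each can take:
#' floor color (10), wall color (10), object color (4), object scale (4),
#' object shape (4), object orientation (15). All indices are 0-based.
#'
#' @return Named integer vector of factor cardinalities.
#' @export
factor_levels <- function() {
  c(floor_color = 10L, wall_color = 10L, object_color = 4L,
    object_scale = 4L, object_shape = 4L, orientation = 15L)
}

#' Attribute names defining an object class
#' @return Character vector `c("color", "scale", "shape")`.
#' @export
class_attributes <- function() c("color", "scale", "shape")

#' Construct validated latent-factor combinations
#'
#' @param floor_color,wall_color Integers in 0..9.
#' @param object_color,object_scale,object_shape Integers in 0..3.
#' @param orientation Integer in 0..14.
#' @return A data.frame with one row per combination (arguments are recycled).
#' @export
latent_factors <- function(floor_color = 0L, wall_color = 0L, object_color = 0L,
                           object_scale = 0L, object_shape = 0L, orientation = 0L) {
  df <- data.frame(floor_color = as.integer(floor_color),
                   wall_color = as.integer(wall_color),
                   object_color = as.integer(object_color),
                   object_scale = as.integer(object_scale),
                   object_shape = as.integer(object_shape),
                   orientation = as.integer(orientation))
  validate_latents(df)
  df
}

validate_latents <- function(latents) {
  lv <- factor_levels()
  assert_that(is.data.frame(latents) && all(names(lv) %in% names(latents)),
              "latents must be a data.frame with the six factor columns")
  for (f in names(lv)) {
    x <- latents[[f]]
    assert_that(all(!is.na(x)) && all(x >= 0L) && all(x < lv[[f]]),
                sprintf("latent factor '%s' out of range [0, %d]", f, lv[[f]] - 1L))
  }
  invisible(latents)
}

#' Map latent factors to the 64-way object class
#'
#' Classes are laid out color-major: `class = 16 * color + 4 * scale + shape`
#' (0-based), so the 16 classes of each color form a contiguous block.
#'
#' @param latents A latent-factor data.frame (see [latent_factors()]), or a
#'   data.frame that at least has `object_color`, `object_scale`, `object_shape`.
#' @return A data.frame with `class_index` (0..63) and the three attribute values.
#' @export
class_of <- function(latents) {
  assert_that(is.data.frame(latents) &&
                all(c("object_color", "object_scale", "object_shape") %in% names(latents)),
              "latents must contain object_color, object_scale, object_shape")
  col <- as.integer(latents$object_color)
  sca <- as.integer(latents$object_scale)
  shp <- as.integer(latents$object_shape)
  assert_that(all(col >= 0L & col <= 3L & sca >= 0L & sca <= 3L & shp >= 0L & shp <= 3L),
              "object attribute indices must lie in 0..3")
  data.frame(class_index = 16L * col + 4L * sca + shp,
             color_value = col, scale_value = sca, shape_value = shp)
}

#' Invert the class index back to (color, scale, shape)
#'
#' @param class_index Integer vector in 0..63.
#' @return A data.frame with `class_index`, `color_value`, `scale_value`,
#'   `shape_value`.
#' @export
class_values <- function(class_index) {
  ci <- as.integer(class_index)
  assert_that(all(!is.na(ci) & ci >= 0L & ci <= 63L), "class_index must lie in 0..63")
  data.frame(class_index = ci,
             color_value = ci %/% 16L,
             scale_value = (ci %% 16L) %/% 4L,
             shape_value = ci %% 4L)
}

#' Enumerate every latent-factor combination
#'
#' @return A data.frame with `10*10*4*4*4*15 = 96000` rows.
#' @export
enumerate_latents <- function() {
  lv <- factor_levels()
  g <- expand.grid(floor_color = 0:(lv["floor_color"] - 1L),
                   wall_color = 0:(lv["wall_color"] - 1L),
                   object_color = 0:(lv["object_color"] - 1L),
                   object_scale = 0:(lv["object_scale"] - 1L),
                   object_shape = 0:(lv["object_shape"] - 1L),
                   orientation = 0:(lv["orientation"] - 1L),
                   KEEP.OUT.ATTRS = FALSE)
  g[] <- lapply(g, as.integer)
  g
}

# Room palettes: ten evenly spaced hues for floor and wall. Object colors are
# fixed anchors for red / yellow / turquoise / purple.
room_palette <- function(v = 0.75, s = 0.65) {
  t(grDevices::col2rgb(grDevices::hsv((0:9) / 10, s, v)) / 255)
}

#' Object color palette (red, yellow, turquoise, purple)
#' @return 4 x 3 matrix of RGB values in \[0, 1\].
#' @export
object_palette <- function() {
  rbind(red = c(0.90, 0.10, 0.10),
        yellow = c(0.95, 0.85, 0.10),
        turquoise = c(0.15, 0.80, 0.75),
        purple = c(0.55, 0.15, 0.75))
}

# Logical mask of the object silhouette for one latent row, at a given
# resolution. Shape proxies: square (cube), disc (sphere), capped rectangle
# (cylinder), ellipse (ellipsoid); area grows with the scale index and the
# silhouette is rotated by the orientation index.
stimulus_mask <- function(latents, size = 64L) {
  validate_latents(latents)
  assert_that(nrow(latents) == 1L, "stimulus_mask() expects a single latent row")
  xy <- (seq_len(size) - 0.5) / size
  X <- matrix(xy, size, size, byrow = TRUE)   # column coordinate
  Y <- matrix(xy, size, size)                 # row coordinate (top = 0)
  cx <- 0.5; cy <- 0.52
  h <- 0.11 + 0.05 * latents$object_scale
  theta <- (latents$orientation / 14 - 0.5) * pi / 3  # -30..30 degrees
  u <- cos(theta) * (X - cx) + sin(theta) * (Y - cy)
  v <- -sin(theta) * (X - cx) + cos(theta) * (Y - cy)
  switch(latents$object_shape + 1L,
         abs(u) <= 0.85 * h & abs(v) <= 0.85 * h,                    # cube
         u^2 + v^2 <= h^2,                                           # sphere
         (abs(u) <= 0.62 * h & v >= -0.40 * h & v <= h) |            # cylinder
           (u^2 + (v + 0.40 * h)^2 <= (0.62 * h)^2),
         (u / h)^2 + (v / (0.55 * h))^2 <= 1)                        # ellipsoid
}

#' Render a stimulus image from latent factors
#'
#' Deterministic 2-D proxy renderer: a floor band at the bottom in the floor
#' palette color, the remainder in the wall palette color, and a centered
#' filled shape in the object palette color whose silhouette encodes object
#' shape, whose area encodes object scale, and which is rotated according to
#' the orientation index.
#'
#' @param latents A single-row latent-factor data.frame.
#' @param size Image side length in pixels (default 64).
#' @return A `size x size x 3` array of values in \[0, 1\].
#' @export
render_stimulus <- function(latents, size = 64L) {
  validate_latents(latents)
  assert_that(nrow(latents) == 1L, "render_stimulus() expects a single latent row")
  size <- as.integer(size)
  room <- room_palette()
  obj <- object_palette()
  img <- array(0, c(size, size, 3L))
  floor_rows <- (seq_len(size) - 0.5) / size > 0.72
  for (ch in 1:3) {
    plane <- matrix(room[latents$wall_color + 1L, ch], size, size)
    plane[floor_rows, ] <- room[latents$floor_color + 1L, ch]
    img[, , ch] <- plane
  }
  mask <- stimulus_mask(latents, size)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- obj[latents$object_color + 1L, ch]
    img[, , ch] <- plane
  }
  img
}

#' Render a batch of stimuli
#'
#' @param latents A latent-factor data.frame (one image per row).
#' @param size Image side length in pixels.
#' @return A `size x size x 3 x n` array.
#' @export
render_batch <- function(latents, size = 64L) {
  validate_latents(latents)
  n <- nrow(latents)
  out <- array(0, c(size, size, 3L, n))
  for (i in seq_len(n)) out[, , , i] <- render_stimulus(latents[i, , drop = FALSE], size)
  out
}

#' Sample instances of object classes
#'
#' Draws the class-irrelevant factors (floor color, wall color, orientation)
#' uniformly at random while fixing (color, scale, shape) to the requested
#' class.
#'
#' @param class_index Integer vector of classes in 0..63 (recycled to `n`).
#' @param n Number of instances to draw.
#' @param seed Optional integer seed for reproducibility.
#' @return A latent-factor data.frame with `n` rows.
#' @export
sample_instance <- function(class_index, n = length(class_index), seed = NULL) {
  cv <- class_values(rep_len(as.integer(class_index), n))
  lv <- factor_levels()
  with_local_seed(seed, {
    latent_factors(floor_color = sample.int(lv["floor_color"], n, replace = TRUE) - 1L,
                   wall_color = sample.int(lv["wall_color"], n, replace = TRUE) - 1L,
                   object_color = cv$color_value,
                   object_scale = cv$scale_value,
                   object_shape = cv$shape_value,
                   orientation = sample.int(lv["orientation"], n, replace = TRUE) - 1L)
  })
}

#' Draw a balanced random set of latent items
#'
#' Convenience generator for desk-scale data sets: `images_per_class` instances
#' of each of the 64 classes.
#'
#' @param images_per_class Instances per class.
#' @param seed Optional integer seed.
#' @return A latent-factor data.frame with `64 * images_per_class` rows.
#' @export
sample_latents <- function(images_per_class, seed = NULL) {
  sample_instance(rep(0:63, each = images_per_class), seed = seed)
}

#' Stratified train/test split of latent items
#'
#' Splits per class so that each class contributes `fraction` of its items to
#' the training set (rounded; at least preserving disjointness).
#'
#' @param items A latent-factor data.frame.
#' @param fraction Training fraction in (0, 1); default 0.75.
#' @param seed Optional integer seed.
#' @return A list with elements `train`, `test` (latent-factor data.frames),
#'   `fraction` and `seed`.
#' @export
make_split <- function(items, fraction = 0.75, seed = NULL) {
  validate_latents(items)
  assert_that(nrow(items) > 0, "cannot split an empty item set")
  assert_that(fraction > 0 && fraction < 1, "fraction must lie in (0, 1)")
  cls <- class_of(items)$class_index
  present <- sort(unique(cls))
  counts <- table(cls)
  assert_that(all(counts > 0), "every class must have at least one item")
  idx_train <- with_local_seed(seed, {
    unlist(lapply(present, function(k) {
      idx <- which(cls == k)
      n_tr <- round(length(idx) * fraction)
      n_tr <- max(min(n_tr, length(idx) - 1L), 1L)
      if (length(idx) == 1L) return(idx)  # degenerate: single item goes to train
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  idx_train <- sort(idx_train)
  list(train = items[idx_train, , drop = FALSE],
       test = items[setdiff(seq_len(nrow(items)), idx_train), , drop = FALSE],
       fraction = fraction, seed = seed)
}

#' Data set manifest
#'
#' @param latents A latent-factor data.frame.
#' @return The latents with a `class_index` column appended.
#' @export
dataset_manifest <- function(latents) {
  validate_latents(latents)
  cbind(latents, class_index = class_of(latents)$class_index)
}

#' Export a rendered stimulus as PNG
#'
#' @param latents Single-row latent-factor data.frame.
#' @param file Output path.
#' @param size Image side length in pixels.
#' @return The file path, invisibly.
#' @export
export_stimulus_png <- function(latents, file, size = 64L) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_refgame("package 'png' is required for PNG export")
  }
  png::writePNG(render_stimulus(latents, size), file)
  invisible(file)
}

#' Load the real 3dshapes data set (optional interface)
#'
#' Accepts either a path to the 3dshapes HDF5 file (requires the 'hdf5r'
#' package) or a list with elements `images` (N x 64 x 64 x 3, values 0..255
#' or 0..1) and `labels` (N x 6 matrix of factor values). The data are
#' subset to the four object colors and four object scales used here
#' (colors at hue indices 0, 3, 6, 9 of the native 10; scales at indices
#' 0, 2, 4, 7 of the native 8, i.e. equally spaced from smallest to largest)
#' and converted to latent indices plus class labels.
#'
#' @param x Path to an HDF5 file or a list with `images` and `labels`.
#' @return A list with `images` (64 x 64 x 3 x n array in \[0,1\]), `latents`
#'   and `class_index`.
#' @export
load_3dshapes <- function(x) {
  if (is.character(x)) {
    if (!requireNamespace("hdf5r", quietly = TRUE)) {
      stop_refgame("reading the 3dshapes HDF5 file requires the 'hdf5r' package; ",
                   "alternatively pass a list(images=, labels=) read elsewhere")
    }
    f <- hdf5r::H5File$new(x, mode = "r")
    on.exit(f$close_all())
    x <- list(images = f[["images"]]$read(), labels = f[["labels"]]$read())
  }
  assert_that(is.list(x) && !is.null(x$images) && !is.null(x$labels),
              "expected a list with 'images' and 'labels'")
  labels <- x$labels
  # native columns: floor hue, wall hue, object hue, scale, shape, orientation
  hue_idx <- function(h) as.integer(round(h * 9))        # hues are i/10 for i=0..9
  used_colors <- c(0L, 3L, 6L, 9L)
  native_scales <- sort(unique(labels[, 4]))
  used_scales <- native_scales[round(seq(1, length(native_scales), length.out = 4))]
  ori_vals <- sort(unique(labels[, 6]))
  keep <- hue_idx(labels[, 3]) %in% used_colors & labels[, 4] %in% used_scales
  labels <- labels[keep, , drop = FALSE]
  imgs <- x$images
  if (length(dim(imgs)) == 4 && dim(imgs)[1] == sum(keep) + sum(!keep)) {
    imgs <- imgs[keep, , , , drop = FALSE]
    imgs <- aperm(imgs, c(2, 3, 4, 1))
  }
  if (max(imgs) > 1) imgs <- imgs / 255
  latents <- latent_factors(
    floor_color = hue_idx(labels[, 1]),
    wall_color = hue_idx(labels[, 2]),
    object_color = match(hue_idx(labels[, 3]), used_colors) - 1L,
    object_scale = match(labels[, 4], used_scales) - 1L,
    object_shape = as.integer(labels[, 5]),
    orientation = match(labels[, 6], ori_vals) - 1L)
  list(images = imgs, latents = latents, class_index = class_of(latents)$class_index)
}
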