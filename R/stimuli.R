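# Parametric cartoon-face stimuli.
#
# Identity is carried exclusively by the eyes and nose; expression exclusively
# by the eyebrows and mouth.  Each feature lives in its own horizontal band of
# the image so that the pixel support of identity features and expression
# features is disjoint for every combination, which is the property the
# training experiment exploits.  All geometry interpolates linearly across the
# transform index, giving two smooth, unidimensional stimulus spaces.
#
# Features are rasterised through a signed inside-ness field s (in pixels,
# positive inside the shape) converted to an edge coverage value
# clamp(s + 1/2, 0, 1), i.e. a deterministic one-pixel-wide soft edge.  This
# uses the full 256-grey-level range and guarantees that a sub-pixel change in
# geometry still changes the rendered image, so all transforms are distinct.

# Geometry constants, in pixels on the reference 128x128 canvas.  Bands
# (rows, top to bottom): eyebrows ~27..36, eyes ~44..62, nose ~66..88,
# mouth ~92..114.  Feature excursions are bounded so identity and expression
# supports (including the soft edge) never intersect at any transform.
.face_geometry <- list(
  canvas       = 128,
  outline      = 1.0,                 # stroke half-width of outlined features
  eye          = list(cy0 = 48, cy1 = 8, dx0 = 15, dx1 = 7,
                      rx0 = 5, rx1 = 3.5, ry0 = 3, ry1 = 2.5),
  nose         = list(top0 = 66, top1 = 4, h0 = 12, h1 = 6, hw0 = 4, hw1 = 4),
  brow         = list(dx = 18, halflen = 8, y0 = 30, lift = 4,
                      tilt = 6, thick = 1.0),
  mouth        = list(cy0 = 97, cy1 = 12, hw0 = 12, hw1 = 8,
                      curv0 = -0.065, curv1 = 0.13, thick = 1.0)
)

.face_modes <- c("complete", "identity_only", "expression_only")

.check_transform_index <- function(k, n, what) {
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 1 || k > n)
    stop(sprintf("%s index must be a single integer in 1..%d (got %s)",
                 what, n, paste(k, collapse = ",")), call. = FALSE)
  as.integer(k)
}

# pixel-centre coordinate grids (row = y, increasing downwards)
.pixel_grid <- function(size) {
  .cache_get(paste0("grid", size), function() {
    list(Y = matrix(seq_len(size), size, size),
         X = matrix(seq_len(size), size, size, byrow = TRUE))
  })
}

.coverage <- function(s) pmin(pmax(s + 0.5, 0), 1)

# signed inside-ness fields, approximate Euclidean distance to the boundary
.ellipse_field <- function(g, cx, cy, rx, ry) {
  q <- sqrt(((g$X - cx) / rx)^2 + ((g$Y - cy) / ry)^2)
  (1 - q) * min(rx, ry)
}

# filled triangle: apex at (cx, ytop), base half-width hw at ybot
.triangle_field <- function(g, cx, ytop, ybot, hw) {
  frac <- (g$Y - ytop) / (ybot - ytop)
  lateral <- hw * frac - abs(g$X - cx)
  slope <- sqrt(1 + (hw / (ybot - ytop))^2)
  pmin(g$Y - ytop, ybot - g$Y, lateral / slope)
}

# thick stroke along y = fy(x), x in [x0, x1], with rounded end caps
.stroke_field <- function(g, x0, x1, fy, thick) {
  xc <- pmin(pmax(g$X, x0), x1)
  d <- sqrt((g$X - xc)^2 + (g$Y - fy(xc))^2)
  thick - d
}

.identity_coverage_raw <- function(ti, size) {
  gm <- .face_geometry
  sc <- size / gm$canvas
  g <- .pixel_grid(size)
  cx <- (size + 1) / 2
  thick <- max(gm$outline * sc, 1)
  e <- gm$eye
  cy <- (e$cy0 + e$cy1 * ti) * sc
  dx <- (e$dx0 + e$dx1 * ti) * sc
  rx <- (e$rx0 + e$rx1 * ti) * sc
  ry <- (e$ry0 + e$ry1 * ti) * sc
  # outlined (line-drawing) features: stroke along the shape boundary
  s <- pmax(thick - abs(.ellipse_field(g, cx - dx, cy, rx, ry)),
            thick - abs(.ellipse_field(g, cx + dx, cy, rx, ry)))
  n <- gm$nose
  ytop <- (n$top0 + n$top1 * ti) * sc
  ybot <- ytop + (n$h0 + n$h1 * ti) * sc
  hw <- (n$hw0 + n$hw1 * ti) * sc
  s <- pmax(s, thick - abs(.triangle_field(g, cx, ytop, ybot, hw)))
  .coverage(s)
}

.expression_coverage_raw <- function(te, size) {
  gm <- .face_geometry
  sc <- size / gm$canvas
  g <- .pixel_grid(size)
  cx <- (size + 1) / 2
  b <- gm$brow
  y0 <- (b$y0 + b$lift * te) * sc
  dh <- b$tilt * (2 * te - 1) * sc     # inner-end minus outer-end height
  L <- b$halflen * sc
  bx <- b$dx * sc
  thick <- max(b$thick * sc, 1)
  # brows tilt symmetrically: inner ends rise/fall together across expression
  s <- pmax(
    .stroke_field(g, cx - bx - L, cx - bx + L,
                  function(x) y0 + dh * (x - (cx - bx - L)) / (2 * L) - dh / 2,
                  thick),
    .stroke_field(g, cx + bx - L, cx + bx + L,
                  function(x) y0 + dh * ((cx + bx + L) - x) / (2 * L) - dh / 2,
                  thick))
  mo <- gm$mouth
  cy <- (mo$cy0 + mo$cy1 * te) * sc
  hw <- (mo$hw0 + mo$hw1 * te) * sc
  k <- (mo$curv0 + mo$curv1 * te) / sc
  s <- pmax(s, .stroke_field(g, cx - hw, cx + hw,
                             function(x) cy + k * ((x - cx)^2 - hw^2 / 2),
                             max(mo$thick * sc, 1)))
  .coverage(s)
}

# coverages are pure functions of (t, size); cache them so assembling the
# full 40x40 stimulus grid renders each feature set once, not 1600 times
.identity_coverage <- function(ti, size) {
  .cache_get(sprintf("idcov|%.15g|%d", ti, size),
             function() .identity_coverage_raw(ti, size))
}

.expression_coverage <- function(te, size) {
  .cache_get(sprintf("excov|%.15g|%d", te, size),
             function() .expression_coverage_raw(te, size))
}

.transform_scalar <- function(k, n) if (n > 1) (k - 1) / (n - 1) else 0.5

#' Render one cartoon face
#'
#' Draws a single face stimulus as dark features (grey level 0) on a light
#' background (grey level 255).  The eyes and nose depend only on the
#' identity index; the eyebrows and mouth depend only on the expression
#' index, and the two feature sets occupy disjoint pixel bands, so the
#' complete face is the pixelwise union (darker-of) of the two isolated
#' renders.  Rendering is deterministic: the same parameters always produce
#' a bit-identical image.
#'
#' @param identity integer identity transform index in `1..n_identity`.
#' @param expression integer expression transform index in `1..n_expression`.
#' @param mode `"complete"` (default), `"identity_only"` or
#'   `"expression_only"`.
#' @param size image side in pixels (default 128).
#' @param n_identity,n_expression number of transforms along each space
#'   (default 40 each).
#' @return an integer `size` x `size` matrix of grey levels in 0..255 with
#'   class `"face_stimulus"` and attributes `label`, `identity`,
#'   `expression`.
#' @examples
#' img <- render_face(1, 40)
#' range(img)           # 0 255
#' @export
render_face <- function(identity, expression, mode = "complete",
                        size = 128L, n_identity = 40L, n_expression = 40L) {
  mode <- match.arg(mode, .face_modes)
  i <- .check_transform_index(identity, n_identity, "identity")
  e <- .check_transform_index(expression, n_expression, "expression")
  ti <- .transform_scalar(i, n_identity)
  te <- .transform_scalar(e, n_expression)
  cov <- switch(mode,
    complete        = pmax(.identity_coverage(ti, size),
                           .expression_coverage(te, size)),
    identity_only   = .identity_coverage(ti, size),
    expression_only = .expression_coverage(te, size))
  px <- matrix(as.integer(round(255 * (1 - cov))), size, size)
  structure(px, class = c("face_stimulus", "matrix", "array"),
            label = mode, identity = i, expression = e,
            n_identity = n_identity, n_expression = n_expression)
}

#' Feature support of a face render
#'
#' Logical mask of pixels touched (any darkening) by the given render.
#'
#' @param img a `face_stimulus`.
#' @return logical matrix, `TRUE` where the image differs from background.
#' @export
stimulus_support <- function(img) unclass(img) < 255L

#' Generate the full face stimulus set
#'
#' Produces one image per (identity, expression) combination in identity-major
#' order (identity varies slowest), the order in which stimuli are indexed
#' throughout training and analysis.  The default 40 x 40 grid yields the
#' 1600 training faces.
#'
#' @param n_identity,n_expression grid dimensions (default 40 x 40).
#' @param mode passed to [render_face()].
#' @param size image side in pixels.
#' @return a list of `n_identity * n_expression` `face_stimulus` images;
#'   element `(i - 1) * n_expression + e` is face `(i, e)`.
#' @export
generate_stimulus_set <- function(n_identity = 40L, n_expression = 40L,
                                  mode = "complete", size = 128L) {
  mode <- match.arg(mode, .face_modes)
  out <- vector("list", n_identity * n_expression)
  for (i in seq_len(n_identity)) {
    for (e in seq_len(n_expression)) {
      out[[(i - 1L) * n_expression + e]] <-
        render_face(i, e, mode, size, n_identity, n_expression)
    }
  }
  out
}

#' @export
print.face_stimulus <- function(x, ...) {
  cat(sprintf("<face_stimulus %dx%d  %s  identity %d/%d  expression %d/%d>\n",
              nrow(x), ncol(x), attr(x, "label"),
              attr(x, "identity"), attr(x, "n_identity"),
              attr(x, "expression"), attr(x, "n_expression")))
  invisible(x)
}

#' Write a grey-level image as plain-text PGM
#'
#' @param img integer matrix of grey levels 0..255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  writeLines(apply(img, 1L, paste, collapse = " "), con)
  invisible(path)
}
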