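# Analytic shape primitives for phantom construction. A shape is a named
# list: type "disc" (center, radius), "ellipse" (center, a, b, angleDeg) or
# "box" (center, w, h, angleDeg), plus the material name and a z extent
# (prism along the slice axis; infinite by default). Later shapes paint
# over earlier ones.

shapeDisc <- function(material, center, radius, zRange = c(-Inf, Inf))
  list(type = "disc", material = material, center = center, radius = radius,
       zRange = zRange)

shapeEllipse <- function(material, center, a, b, angleDeg = 0,
                         zRange = c(-Inf, Inf))
  list(type = "ellipse", material = material, center = center,
       a = a, b = b, angleDeg = angleDeg, zRange = zRange)

shapeBox <- function(material, center, w, h, angleDeg = 0,
                     zRange = c(-Inf, Inf))
  list(type = "box", material = material, center = center,
       w = w, h = h, angleDeg = angleDeg, zRange = zRange)

# Rotate a shape by angleDeg about the lab origin (in-plane).
rotateShape <- function(s, angleDeg) {
  th <- angleDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s$center <- as.numeric(R %*% s$center)
  if (!is.null(s$angleDeg)) s$angleDeg <- s$angleDeg + angleDeg
  s
}

# Paint shapes onto an n x n label grid (pixel-center membership test).
# With a non-zero tilt (degrees, about the vertical/y axis) and slice
# height zSlice, the grid holds the oblique cross-section of the tilted
# 3D phantom: a scanner pixel (x', y') in the slice at z' maps back to the
# phantom point (c x' - s z', y', s x' + c z'), which is tested against the
# 2D shape and its z extent. This is what makes tilted acquisitions see
# genuinely different slice geometry (the re-slicing of Figure-1 style
# complementarity) instead of a rotated copy of the same section.
rasterizeShapes <- function(shapes, materials, n, spacing, tiltDeg = 0,
                            zSlice = 0) {
  matNames <- vapply(materials, function(m) m@name, "")
  cx <- (seq_len(n) - (n + 1) / 2) * spacing
  X <- matrix(cx, n, n)
  Y <- matrix(cx, n, n, byrow = TRUE)
  th <- tiltDeg * pi / 180
  PX <- cos(th) * X - sin(th) * zSlice
  PZ <- sin(th) * X + cos(th) * zSlice
  labels <- matrix(1L, n, n)  # air background
  for (s in shapes) {
    idx <- match(s$material, matNames)
    if (is.na(idx)) stop("unknown material: ", s$material)
    zr <- s$zRange %||% c(-Inf, Inf)
    dx <- PX - s$center[1]
    dy <- Y - s$center[2]
    inside <- switch(s$type,
      disc = dx^2 + dy^2 <= s$radius^2,
      ellipse = {
        th <- -(s$angleDeg %||% 0) * pi / 180
        u <- dx * cos(th) - dy * sin(th)
        v <- dx * sin(th) + dy * cos(th)
        (u / s$a)^2 + (v / s$b)^2 <= 1
      },
      box = {
        th <- -(s$angleDeg %||% 0) * pi / 180
        u <- dx * cos(th) - dy * sin(th)
        v <- dx * sin(th) + dy * cos(th)
        abs(u) <= s$w / 2 & abs(v) <= s$h / 2
      },
      stop("unknown shape type: ", s$type))
    inside <- inside & PZ >= zr[1] & PZ <= zr[2]
    labels[inside] <- idx
  }
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a phantom from analytic shapes
#'
#' @param shapes list of shape primitives (see [makeGammexPhantom()] for
#'   ready-made phantoms).
#' @param materials named list of [Material-class]; first entry must be air.
#' @param n grid size (n x n pixels).
#' @param spacing pixel size in cm.
#' @return a [PhantomImage-class].
#' @export
phantomImage <- function(shapes, materials = materialTable(), n = 256,
                         spacing = 0.13) {
  labels <- rasterizeShapes(shapes, materials, n, spacing)
  new("PhantomImage", labels = labels, materials = unname(materials),
      spacing = spacing, shapes = shapes)
}

#' Digital Gammex-like calibration phantom
#'
#' A 33 cm disc of Solid Water with 3 cm cylindrical inserts. The default
#' configuration places a solid 3 cm titanium insert at (10, 0) cm — thick
#' enough that well under 1% of photons survive its 3 cm chord, the photon
#' starvation that drives the streak artifacts — plus a representative set
#' of bone / soft tissue / air / water inserts on the same 10 cm ring,
#' giving the high-contrast neighbours that shape the streak pattern.
#' Evaluation rings around a 3 cm metal insert should start outside its
#' 1.5 cm radius (the shipped experiment uses radii 2.0-2.8 cm).
#'
#' @param insertSpec list of inserts, each `list(material=, center=c(x, y),
#'   diameter=)` (cm). `NULL` gives the default configuration; an empty
#'   `list()` gives the homogeneous disc.
#' @param n,spacing raster size and pixel pitch (cm).
#' @param tiRodDiameter diameter of the titanium insert in cm (default: the full 3 cm insert is titanium).
#' @return a [PhantomImage-class].
#' @examples
#' p <- makeGammexPhantom(n = 128, spacing = 0.26)
#' table(p@labels)
#' @export
makeGammexPhantom <- function(insertSpec = NULL, n = 256, spacing = 0.13,
                              tiRodDiameter = 3) {
  if (is.null(insertSpec)) {
    at <- function(deg, r = 10) r * c(cos(deg * pi / 180), sin(deg * pi / 180))
    insertSpec <- list(
      list(material = "titanium", center = at(0), diameter = tiRodDiameter),
      list(material = "soft_tissue", center = at(45), diameter = 3),
      list(material = "bone", center = at(90), diameter = 3),
      list(material = "soft_tissue", center = at(135), diameter = 3),
      list(material = "bone", center = at(180), diameter = 3),
      list(material = "soft_tissue", center = at(225), diameter = 3),
      list(material = "air", center = at(270), diameter = 3),
      list(material = "water", center = at(315), diameter = 3))
  }
  for (ins in insertSpec) {
    if (sqrt(sum(ins$center^2)) + ins$diameter / 2 > 16.5)
      stop("insert at (", paste(ins$center, collapse = ", "),
           ") falls outside the 33 cm disc")
  }
  # overlap check on the 3 cm slots (a thin rod sits in its own slot)
  ns <- length(insertSpec)
  if (ns > 1) {
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      d <- sqrt(sum((insertSpec[[i]]$center - insertSpec[[j]]$center)^2))
      if (d < (max(insertSpec[[i]]$diameter, 3) +
               max(insertSpec[[j]]$diameter, 3)) / 2)
        stop("overlapping inserts ", i, " and ", j)
    }
  }
  zr <- c(-2.5, 2.5)  # 5 cm disc height
  shapes <- list(shapeDisc("solid_water", c(0, 0), 16.5, zRange = zr))
  for (ins in insertSpec)
    shapes <- c(shapes, list(shapeDisc(ins$material, ins$center,
                                       ins$diameter / 2, zRange = zr)))
  phantomImage(shapes, n = n, spacing = spacing)
}

#' Digital dental phantom
#'
#' A skull-like section: an ellipse of cortical bone enclosing soft tissue,
#' an air-filled mouth cavity, and six disjoint metal restorations on a
#' dental arch — one gold bridge, one steel bridge and four gold crowns.
#' The interior air cavity supports the box-ROI evaluation against
#' c = -1000 HU.
#'
#' @param n,spacing raster size and pixel pitch (cm).
#' @return a [PhantomImage-class].
#' @examples
#' p <- makeDentalPhantom(n = 128, spacing = 0.16)
#' @export
makeDentalPhantom <- function(n = 256, spacing = 0.13) {
  arch <- function(deg, r = 4.2, c0 = c(0, -3))
    c0 + r * c(cos(deg * pi / 180), sin(deg * pi / 180))
  zm <- c(-0.75, 0.75)  # restorations: ~1.5 cm along the slice axis
  shapes <- list(
    shapeEllipse("bone", c(0, 0), 8.0, 10.0, zRange = c(-6, 6)),
    shapeEllipse("soft_tissue", c(0, 0), 7.0, 9.0, zRange = c(-6, 6)),
    # mouth cavity (air) between the jaws
    shapeEllipse("air", c(0, -3), 3.0, 1.9, zRange = c(-2.5, 2.5)),
    # upper arch: gold bridge (left), steel bridge (right), two crowns
    shapeBox("gold", arch(150), 2.2, 0.7, 150 - 90, zRange = zm),
    shapeBox("steel", arch(30), 2.2, 0.7, 30 - 90, zRange = zm),
    shapeDisc("gold", arch(75), 0.35, zRange = zm),
    shapeDisc("gold", arch(105), 0.35, zRange = zm),
    # lower arch: two crowns
    shapeDisc("gold", arch(240, r = 3.4), 0.35, zRange = zm),
    shapeDisc("gold", arch(300, r = 3.4), 0.35, zRange = zm))
  phantomImage(shapes, n = n, spacing = spacing)
}

#' Oblique cross-section of a tilted phantom
#'
#' The 2D section seen by a scanner slice at height `zSlice` when the
#' phantom has been tilted by `tiltDeg` about the vertical (y) axis.
#' Requires an analytic (shape-based) phantom.
#'
#' @param p a [PhantomImage-class] with shapes.
#' @param tiltDeg tilt about the y axis in degrees.
#' @param zSlice scanner-frame slice height in cm.
#' @return a [PhantomImage-class] holding the section (no shapes).
#' @export
phantomSlice <- function(p, tiltDeg = 0, zSlice = 0) {
  if (tiltDeg == 0 && zSlice == 0) return(p)
  if (length(p@shapes) == 0)
    stop("oblique slicing requires an analytic (shape-based) phantom")
  labels <- rasterizeShapes(p@shapes, p@materials, nrow(p@labels),
                            p@spacing, tiltDeg, zSlice)
  new("PhantomImage", labels = labels, materials = p@materials,
      spacing = p@spacing, shapes = list())
}

#' Rotate a phantom in-plane
#'
#' Rotates the phantom by `angleDeg` about the slice normal through the lab
#' origin. Phantoms built from analytic shapes are re-rasterized from the
#' rotated geometry (exact); label grids without shapes fall back to
#' nearest-neighbour resampling.
#'
#' @param p a [PhantomImage-class].
#' @param angleDeg rotation angle in degrees (counter-clockwise).
#' @return a [PhantomImage-class].
#' @export
rotatePhantom <- function(p, angleDeg) {
  if (angleDeg %% 360 == 0) return(p)
  if (length(p@shapes) > 0) {
    shapes <- lapply(p@shapes, rotateShape, angleDeg = angleDeg)
    labels <- rasterizeShapes(shapes, p@materials, nrow(p@labels), p@spacing)
    return(new("PhantomImage", labels = labels, materials = p@materials,
               spacing = p@spacing, shapes = shapes))
  }
  n <- nrow(p@labels)
  th <- -angleDeg * pi / 180  # pull-based
  cx <- (n + 1) / 2
  idx <- seq_len(n) - cx
  X <- matrix(idx, n, n)
  Y <- matrix(idx, n, n, byrow = TRUE)
  sx <- round(X * cos(th) - Y * sin(th) + cx)
  sy <- round(X * sin(th) + Y * cos(th) + cx)
  ok <- sx >= 1 & sx <= n & sy >= 1 & sy <= n
  labels <- matrix(1L, n, n)
  labels[ok] <- p@labels[cbind(sx[ok], sy[ok])]
  new("PhantomImage", labels = labels, materials = p@materials,
      spacing = p@spacing, shapes = list())
}

#' Ideal HU rendering of a phantom
#'
#' Maps each pixel's material to its linear attenuation at the reference
#' energy and converts to HU — the ground truth image that a perfect
#' scanner would reconstruct. Used to isolate artifact-only images
#' (reconstruction minus ground truth).
#'
#' @param p a [PhantomImage-class].
#' @param sliceSpacing slice thickness for the returned single-slice volume
#'   (cm).
#' @return a single-slice [CTVolume-class].
#' @export
idealRendering <- function(p, sliceSpacing = 0.1) {
  mu <- vapply(p@materials, linearAttenuation, 0, energy = REF_ENERGY_KEV)
  hu <- huFromMu(mu)
  img <- matrix(hu[p@labels], nrow(p@labels), ncol(p@labels))
  ctVolume(img, spacing = c(p@spacing, p@spacing, sliceSpacing))
}

setMethod("show", "PhantomImage", function(object) {
  cat(sprintf("PhantomImage %d x %d, pixel %.3g cm, %d materials\n",
              nrow(object@labels), ncol(object@labels), object@spacing,
              length(object@materials)))
  tab <- table(factor(object@labels, levels = seq_along(object@materials),
                      labels = vapply(object@materials,
                                      function(m) m@name, "")))
  print(tab[tab > 0])
})
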