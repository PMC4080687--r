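#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix. Default identity.
#' @param translation numeric(3), cm. Default zero.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Rigid transform from axis and angle
#'
#' Rodrigues' rotation about `axis` by `angleDeg` degrees, plus a
#' translation.
#'
#' @param axis numeric(3) rotation axis (need not be unit length).
#' @param angleDeg rotation angle in degrees.
#' @param translation numeric(3), cm.
#' @return a [RigidTransform-class].
#' @examples
#' t <- axisAngleTransform(c(0, 0, 1), 90)
#' rotation(t) %*% c(1, 0, 0)  # ~ (0, 1, 0)
#' @export
axisAngleTransform <- function(axis, angleDeg, translation = c(0, 0, 0)) {
  n <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigidTransform(R, translation)
}

#' @rdname RigidTransform-class
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)

#' @rdname RigidTransform-class
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)

#' Invert a rigid transform
#'
#' @param t a [RigidTransform-class].
#' @return the inverse transform.
#' @export
invertTransform <- function(t) {
  Ri <- t(t@rotation)
  rigidTransform(Ri, -as.numeric(Ri %*% t@translation))
}

#' Compose two rigid transforms
#'
#' Returns the transform applying `b` first, then `a`:
#' `x -> a(b(x))`.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Apply a rigid transform to points
#'
#' @param t a [RigidTransform-class].
#' @param pts numeric(3) or an n x 3 matrix of lab-frame points (cm).
#' @return transformed points, same shape as `pts`.
#' @export
applyTransform <- function(t, pts) {
  if (is.null(dim(pts))) return(as.numeric(t@rotation %*% pts + t@translation))
  sweep(pts %*% t(t@rotation), 2, t@translation, "+")
}

setMethod("show", "RigidTransform", function(object) {
  aa <- rotationToAxisAngle(object@rotation)
  cat(sprintf(
    "RigidTransform: %.3f deg about (%.3f, %.3f, %.3f), shift (%s) cm\n",
    aa$angle, aa$axis[1], aa$axis[2], aa$axis[3],
    paste(signif(object@translation, 4), collapse = ", ")))
})

# Axis-angle decomposition of a proper rotation matrix (angle in degrees,
# in [0, 180]; axis arbitrary for the identity).
rotationToAxisAngle <- function(R) {
  ctheta <- (sum(diag(R)) - 1) / 2
  ctheta <- min(1, max(-1, ctheta))
  theta <- acos(ctheta)
  if (theta < 1e-9) return(list(axis = c(0, 0, 1), angle = 0))
  if (pi - theta < 1e-6) {
    # near 180 deg: axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    k <- which.max(axis)
    sgn <- sign(B[k, ]); sgn[sgn == 0] <- 1
    axis <- axis * sgn / sgn[k]
    axis <- axis / sqrt(sum(axis^2))
    return(list(axis = axis, angle = theta * 180 / pi))
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  list(axis = axis, angle = theta * 180 / pi)
}

#' Read and write rigid transforms as plain text
#'
#' One transform per file: axis (3 numbers), angle in degrees, translation
#' in cm, as `key value...` lines. Round trips exactly to printed precision
#' (17 significant digits).
#'
#' @param t a [RigidTransform-class].
#' @param path file path.
#' @return `readTransform` returns a [RigidTransform-class];
#'   `writeTransform` returns `path` invisibly.
#' @export
writeTransform <- function(t, path) {
  aa <- rotationToAxisAngle(t@rotation)
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(paste("axis", num(aa$axis)),
             paste("angle_deg", num(aa$angle)),
             paste("translation_cm", num(t@translation)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  lines <- readLines(path)
  get1 <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (length(ln) != 1L) stop("transform file missing field: ", key)
    parts <- strsplit(sub(paste0("^", key, " +"), "", ln), " +")[[1]]
    as.numeric(parts[nzchar(parts)])
  }
  axisAngleTransform(get1("axis"), get1("angle_deg"), get1("translation_cm"))
}
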