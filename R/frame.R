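## Anatomical coordinate frame from the three registration landmarks.
##
## Origin: midpoint between the preauricular points.  +X points toward the
## glabella, +Y is the component of (left - right preauricular) orthogonal to
## X (so +Y is the patient's left), Z = X x Y (right-handed, roughly superior).

#' Align a head model to its anatomical frame
#'
#' Applies the rigid transform (rotation + translation, determinant +1) that
#' maps the inter-preauricular midpoint to the origin, the glabella onto the
#' positive X axis, and makes the two preauricular points symmetric about the
#' X–Z plane (equal-magnitude opposite-sign y, equal z).  Landmarks are
#' transformed consistently and kept on the returned model.
#'
#' @param model a [head_model()] carrying landmarks.
#' @return The aligned `head_model` (`is_aligned = TRUE`).
#' @export
align_head <- function(model) {
  stopifnot(inherits(model, "head_model"))
  lm <- model$landmarks
  if (is.null(lm))
    stop_craniosh("precondition", "head '%s' has no landmarks to align with", model$id)

  origin <- (lm$preauricular_left + lm$preauricular_right) / 2
  xv <- lm$glabella - origin
  if (vnorm(xv) < .Machine$double.eps^0.5)
    stop_craniosh("geometry", "glabella coincides with the inter-preauricular midpoint")
  x <- unit(xv)
  yraw <- lm$preauricular_left - lm$preauricular_right
  yperp <- yraw - sum(yraw * x) * x
  if (vnorm(yperp) < 1e-9 * vnorm(yraw))
    stop_craniosh("geometry", "glabella lies on the preauricular axis; frame undefined")
  y <- unit(yperp)
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  R <- rbind(x, y, z)  # rows are the new axes: new = R (p - origin)

  transform <- function(p) {
    if (is.matrix(p)) t(R %*% (t(p) - origin)) else as.vector(R %*% (p - origin))
  }
  new_lm <- landmarks_new(transform(lm$preauricular_left),
                          transform(lm$preauricular_right),
                          transform(lm$glabella))
  head_model(transform(model$points), id = model$id,
             landmarks = new_lm, is_aligned = TRUE)
}
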