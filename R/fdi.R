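#' FDI notation arithmetic
#'
#' The FDI (Federation Dentaire Internationale) two-digit notation encodes a
#' permanent tooth as `10 * quadrant + position`, with quadrant 1 = upper
#' right, 2 = upper left, 3 = lower left, 4 = lower right, and position 1
#' (central incisor) through 8 (third molar) counted from the midline.
#' These helpers validate codes, decompose them, mirror them across the
#' midsagittal plane and enumerate canonical arch sequences. Label 0 is
#' reserved for gingiva/background in annotation files and is never a valid
#' `FdiLabel`.
#'
#' @name fdi
NULL

#' All 32 permanent-dentition FDI labels
#'
#' @return Integer vector of the 32 valid codes, upper arch first.
#' @export
fdi_labels <- function() {
  c(11:18, 21:28, 31:38, 41:48)
}

#' Validate FDI labels
#'
#' @param label Integer vector of candidate codes.
#' @return `label`, invisibly coerced to integer, if all codes are valid.
#'   Invalid codes (including primary-dentition 51-85) raise an error.
#' @export
validate_fdi <- function(label) {
  if (length(label) == 0L) {
    stop("no FDI label supplied", call. = FALSE)
  }
  lab <- suppressWarnings(as.integer(label))
  bad <- is.na(lab) | !(lab %in% fdi_labels())
  if (any(bad)) {
    stop(
      "invalid FDI label(s): ", paste(unique(label[bad]), collapse = ", "),
      " (expected two-digit codes, quadrant 1-4, position 1-8)",
      call. = FALSE
    )
  }
  invisible(lab)
}

#' Decompose an FDI code into quadrant and position digits
#'
#' @param label Integer vector of valid FDI codes.
#' @return A list with integer components `quadrant` (1-4) and
#'   `position` (1-8).
#' @examples
#' quadrant_position(11) # quadrant 1, position 1
#' quadrant_position(48) # quadrant 4, position 8
#' @export
quadrant_position <- function(label) {
  lab <- validate_fdi(label)
  list(quadrant = lab %/% 10L, position = lab %% 10L)
}

#' Mirror an FDI label across the midsagittal plane
#'
#' Swaps quadrant 1 with 2 and 3 with 4 while preserving the position digit,
#' e.g. 21 -> 11 and 16 -> 26. Mirroring is an involution.
#'
#' @param label Integer vector of valid FDI codes.
#' @return Integer vector of mirrored codes.
#' @export
mirror_fdi <- function(label) {
  qp <- quadrant_position(label)
  mq <- c(2L, 1L, 4L, 3L)[qp$quadrant]
  mq * 10L + qp$position
}

#' Arch membership of an FDI label
#'
#' @param label Integer vector of valid FDI codes.
#' @return Character vector, `"upper"` (quadrants 1, 2) or `"lower"`
#'   (quadrants 3, 4).
#' @export
arch_of <- function(label) {
  qp <- quadrant_position(label)
  ifelse(qp$quadrant <= 2L, "upper", "lower")
}

#' Canonical left-to-right arch sequence
#'
#' Enumerates the 16 labels of one arch in spatially continuous order along
#' the dental arch. In the standardized frame used throughout this package
#' the traversal starts in quadrant 1 (upper) or 4 (lower) and ends in
#' quadrant 2 or 3: upper = 18..11, 21..28; lower = 48..41, 31..38.
#'
#' @param arch `"upper"` or `"lower"`.
#' @param direction `"forward"` for the canonical order above,
#'   `"reverse"` for its reversal.
#' @return Integer vector of 16 labels with attributes `arch` and
#'   `direction`.
#' @export
arch_sequence <- function(arch = c("upper", "lower"),
                          direction = c("forward", "reverse")) {
  arch <- match.arg(arch)
  direction <- match.arg(direction)
  seq16 <- if (arch == "upper") {
    c(18:11, 21:28)
  } else {
    c(48:41, 31:38)
  }
  if (direction == "reverse") {
    seq16 <- rev(seq16)
  }
  structure(as.integer(seq16), arch = arch, direction = direction)
}
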