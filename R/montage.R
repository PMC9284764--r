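# 19-channel motor-area montage (10-20 system FC/C/CP rows).

MONTAGE_LABELS <- c("FC1", "FC3", "FC5", "C1", "C3", "C5",
                    "CP1", "CP3", "CP5", "Cz",
                    "FC2", "FC4", "FC6", "C2", "C4", "C6",
                    "CP2", "CP4", "CP6")

#' Motor-area 10-20 montage
#'
#' The 19 electrodes over premotor (FC), motor (C) and postcentral (CP) rows
#' used throughout the pipeline, with 2-D positions on a unit-disc scalp
#' projection: Cz at the origin, the FC/C/CP rows at y = +0.25 / 0 / -0.25,
#' and lateral columns at |x| = 0.2, 0.45, 0.7 (odd numbers left of the
#' midline, even numbers right, as in the 10-20 convention). C3 and C4 sit at
#' (-0.45, 0) and (0.45, 0), where the generator places its hemispheric
#' sources.
#'
#' @return a `montage`: list with `labels` (character, length 19) and
#'   `positions` (19 x 2 matrix, rownames = labels).
#' @export
make_montage <- function() {
  xcol <- c(`1` = 0.2, `2` = 0.2, `3` = 0.45, `4` = 0.45, `5` = 0.7, `6` = 0.7)
  yrow <- c(FC = 0.25, C = 0, CP = -0.25)
  pos <- t(vapply(MONTAGE_LABELS, function(lab) {
    if (lab == "Cz") return(c(0, 0))
    num <- sub("^[A-Za-z]+", "", lab)
    row <- sub("[0-9]+$", "", lab)
    x <- xcol[[num]] * if (as.integer(num) %% 2L == 1L) -1 else 1
    c(x, yrow[[row]])
  }, numeric(2)))
  dimnames(pos) <- list(MONTAGE_LABELS, c("x", "y"))
  structure(list(labels = MONTAGE_LABELS, positions = pos),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage: %d channels (%s ...)>\n",
              length(x$labels), paste(head(x$labels, 4), collapse = ", ")))
  invisible(x)
}
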