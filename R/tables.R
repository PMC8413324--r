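## Published reference tallies and per-subject summaries bundled as data
## functions.  These are the printed validation counts and morphometric
## summaries for the three adult human subjects (layer III of Brodmann
## area 46) that the metric and aggregation helpers are checked against,
## and they double as worked-example inputs.

#' Published pixelwise validation confusion counts
#'
#' Pixel-to-pixel tallies between manually segmented and model-predicted
#' 2048 x 2048 images, for individually trained and combined segmentation
#' models over three subjects.
#'
#' @return data.frame with columns model, subject, TP, FP, FN, TN.
#' @export
pixelwiseValidationCounts <- function() {
  data.frame(
    model = rep(c("individual", "combined"), each = 3),
    subject = rep(1:3, 2),
    TP = c(128937, 83370, 91266, 119351, 77409, 92189),
    FP = c(11710, 14400, 10717, 9506, 12994, 12337),
    FN = c(19923, 17810, 11512, 29509, 20717, 8931),
    TN = c(4033734, 4078724, 4080809, 4035938, 4083184, 4080847))
}

#' Published objectwise validation counts
#'
#' Centroid-in-profile matching tallies for 3D-reconstructed pyramidal
#' cells from a 30-section validation stack: `original` uses all sections,
#' `filtered` excludes centroids from the first and last three sections.
#'
#' @return data.frame with columns stack, TP, FN, FP.
#' @export
objectwiseValidationCounts <- function() {
  data.frame(stack = c("original", "filtered"),
             TP = c(472, 368), FN = c(19, 6), FP = c(33, 29))
}

#' Published per-subject morphometric means for layer III pyramidal cells
#'
#' Mean volume (um^3), folded orientation angle (degrees), sphericity, and
#' nucleator diameters from the largest profile (diaL) and from all
#' profiles (diaAll), one row per subject.
#'
#' @return data.frame with a `subject` column and one column per measure.
#' @export
subjectMorphometryTable <- function() {
  data.frame(subject = 1:3,
             volume = c(867, 709, 808),
             orientation = c(34, 28, 24),
             sphericity = c(0.38, 0.33, 0.35),
             diaL = c(11.13, 11.13, 11.27),
             diaAll = c(7.23, 6.49, 7.37))
}

#' Published areal shrinkage measurements
#'
#' Areal shrinkage fractions of three resin-embedded gray-matter biopsies
#' measured before and after processing.
#'
#' @return numeric vector of shrinkage fractions.
#' @export
arealShrinkageReference <- function() {
  c(0.001, 0.042, 0.079)
}
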