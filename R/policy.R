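# Domain-knowledge constraint on prototype candidates: per modality and
# class, only lesions from a restricted set of ordinal grades may donate
# prototype patches. The defaults encode standard breast-ultrasound practice
# on the BI-RADS-like 5-level scale (3, 4a, 4b, 4c, 5): borderline grade 4b
# is never a candidate; B-mode and colour Doppler prototypes come from
# grades {3, 4a} (benign) versus {4c, 5} (malignant); elastography, whose
# acquisition is most operator-sensitive, uses only the extremes {3} versus
# {5}.

#' Prototype candidate policy
#'
#' @param allowed_grades named list: one element per modality, each a list
#'   with components `benign` and `malignant` giving character vectors of
#'   allowed grades. The default restricts B-mode/Doppler to 3,4a vs 4c,5 and
#'   elastography to 3 vs 5.
#' @return object of class `candidate_policy`.
#' @export
candidate_policy <- function(allowed_grades = NULL) {
  if (is.null(allowed_grades)) {
    bd <- list(benign = c("3", "4a"), malignant = c("4c", "5"))
    allowed_grades <- list(bmode = bd, doppler = bd,
                           elasto = list(benign = "3", malignant = "5"))
  }
  for (mod in names(allowed_grades)) {
    ag <- allowed_grades[[mod]]
    stopifnot(all(c("benign", "malignant") %in% names(ag)))
    bad <- setdiff(unlist(ag), GRADE_LEVELS)
    if (length(bad)) stopf("unknown grade(s) in policy: %s", paste(bad, collapse = ", "))
  }
  structure(list(allowed_grades = allowed_grades), class = "candidate_policy")
}

#' Allow-all candidate policy
#'
#' Disables grade filtering (projection reduces to plain
#' nearest-patch-of-class).
#'
#' @param modalities modality names.
#' @return a [candidate_policy()] admitting every grade for both classes.
#' @export
allow_all_policy <- function(modalities = DEFAULT_MODALITIES) {
  ag <- stats::setNames(rep(list(list(benign = GRADE_LEVELS,
                                      malignant = GRADE_LEVELS)),
                            length(modalities)), modalities)
  candidate_policy(ag)
}

#' Prototype candidate mask
#'
#' For a set of lesions, marks which are eligible prototype donors for a
#' given modality and target class: the label must equal the target class
#' and the grade must be in the policy's allowed set.
#'
#' @param grades character vector of ordinal grades.
#' @param labels integer vector of 0/1 labels (same length).
#' @param modality_name modality, e.g. `"elasto"`.
#' @param target_class 0 (benign) or 1 (malignant).
#' @param policy a [candidate_policy()].
#' @return logical vector.
#' @export
candidate_mask <- function(grades, labels, modality_name, target_class,
                           policy = candidate_policy()) {
  stopifnot(length(grades) == length(labels))
  grades <- as.character(grades)
  bad <- setdiff(grades, GRADE_LEVELS)
  if (length(bad)) stopf("unknown grade symbol(s): %s", paste(unique(bad), collapse = ", "))
  ag <- policy$allowed_grades[[modality_name]]
  if (is.null(ag)) stopf("unknown modality '%s' in candidate policy", modality_name)
  allowed <- if (target_class == 1L) ag$malignant else ag$benign
  labels == target_class & grades %in% allowed
}
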