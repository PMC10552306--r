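#' Functional-class vocabularies for annotated exome variants
#'
#' Variants are assigned to Annovar-style functional classes and summarized
#' per gene as a C-dimensional count histogram (the gene's *mutational load*).
#' The shipped default has `C = 16` classes, obtained by merging the two
#' rare stop/start-altering classes (`stoploss`, `startloss`) into one; the
#' full 17-name list is available with `annovar_classes(17)` for pipelines
#' that keep them separate.
#'
#' @param n Either 16 (default, merged vocabulary) or 17 (full list).
#' @return A `class_vocab` object (ordered character vector of class names).
#' @export
#' @examples
#' annovar_classes()       # 16 classes
#' annovar_classes(17)     # full list
annovar_classes <- function(n = 16) {
  full <- c(
    "UTR3", "UTR5", "splicing", "upstream", "downstream", "intronic",
    "ncRNA_intronic", "ncRNA_exonic", "ncRNA_splicing",
    "nonframeshift_insertion", "frameshift_insertion",
    "nonframeshift_deletion", "frameshift_deletion",
    "stoploss", "stopgain", "startloss", "nonsynonymous")
  if (n == 17) return(class_vocabulary(full))
  if (n == 16) {
    merged <- c(setdiff(full, c("stoploss", "startloss", "stopgain",
                                "nonsynonymous")),
                "stoploss_startloss", "stopgain", "nonsynonymous")
    return(class_vocabulary(merged))
  }
  stop("n must be 16 or 17")
}

#' Construct a functional-class vocabulary
#'
#' @param classes Ordered character vector of unique class names (length >= 1).
#' @return A `class_vocab` object.
#' @export
class_vocabulary <- function(classes) {
  classes <- as.character(classes)
  assert_that(length(classes) >= 1, "vocabulary must have at least one class")
  assert_that(!anyDuplicated(classes), "class names must be unique")
  structure(classes, class = "class_vocab")
}

#' @export
print.class_vocab <- function(x, ...) {
  cat("<class_vocab> C =", length(x), "\n ", paste(unclass(x), collapse = ", "),
      "\n")
  invisible(x)
}
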