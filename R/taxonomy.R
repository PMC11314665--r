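# Object-class taxonomy: loading, role queries, writing.

#' Load an object-class taxonomy
#'
#' Loads either the built-in 18-class taxonomy used for egocentric fall-risk
#' contextualization (4 categories: room/environment context, context +
#' fall-risk, fall-risk, privacy) or a user-supplied tab-delimited file with
#' columns `name`, `category`, `roles` (comma-separated tokens out of
#' `context`, `fall_risk`, `privacy`) and optionally `rationale`.
#'
#' Class names are matched case-insensitively after trimming whitespace but
#' stored canonically as written in the source table.
#'
#' @param source `"builtin"` (default) or a path to a delimited file.
#' @return A validated [ClassTaxonomy-class].
#' @export
#' @examples
#' tax <- loadTaxonomy()
#' length(tax)
#' privacyClasses(tax)
loadTaxonomy <- function(source = "builtin") {
  path <- if (identical(source, "builtin")) {
    system.file("extdata", "taxonomy.tsv", package = "egogait", mustWork = TRUE)
  } else {
    source
  }
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  cls <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t",
                           quote = "", comment.char = "#")
  if (nrow(cls) == 0) stop("empty taxonomy file: ", path)
  if (!"rationale" %in% names(cls)) cls$rationale <- ""
  cls$name <- trimws(cls$name)
  cls$roles <- gsub("[[:space:]]", "", cls$roles)
  cls$category <- as.integer(cls$category)
  new("ClassTaxonomy", classes = cls[, c("name", "category", "roles", "rationale")])
}

#' Write a taxonomy to a tab-delimited file
#'
#' The written file round-trips through [loadTaxonomy()] to an identical
#' taxonomy.
#'
#' @param taxonomy A [ClassTaxonomy-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  stopifnot(is(taxonomy, "ClassTaxonomy"))
  utils::write.table(taxonomy@classes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Resolve (possibly vectorized) class names case-insensitively; errors on
# unknown names.
resolveClass <- function(taxonomy, name) {
  idx <- match(tolower(trimws(name)), tolower(taxonomy@classes$name))
  if (anyNA(idx)) {
    stop("class name(s) not in taxonomy: ",
         paste(unique(name[is.na(idx)]), collapse = ", "))
  }
  idx
}

hasRole <- function(taxonomy, name, role) {
  idx <- resolveClass(taxonomy, name)
  vapply(strsplit(taxonomy@classes$roles[idx], ",", fixed = TRUE),
         function(r) role %in% r, logical(1))
}

#' Role queries on a taxonomy
#'
#' `isPrivacyClass()` tests whether classes carry the `privacy` role (their
#' detections must be blurred); `isHazardClass()` tests for the `fall_risk`
#' role (potential extrinsic hazards). Both are vectorized over `name` and
#' raise an error for names not in the taxonomy.
#'
#' @param taxonomy A [ClassTaxonomy-class].
#' @param name Character vector of class names (case-insensitive).
#' @return Logical vector along `name`.
#' @export
#' @examples
#' tax <- loadTaxonomy()
#' isPrivacyClass(tax, c("Screen", "Stairs"))
#' isHazardClass(tax, "Raised kerb")
isPrivacyClass <- function(taxonomy, name) hasRole(taxonomy, name, "privacy")

#' @rdname isPrivacyClass
#' @export
isHazardClass <- function(taxonomy, name) hasRole(taxonomy, name, "fall_risk")

#' @describeIn isPrivacyClass names of all privacy-role classes.
#' @export
privacyClasses <- function(taxonomy) {
  nm <- classNames(taxonomy)
  nm[isPrivacyClass(taxonomy, nm)]
}

#' @describeIn isPrivacyClass names of all fall-risk-role classes.
#' @export
hazardClasses <- function(taxonomy) {
  nm <- classNames(taxonomy)
  nm[isHazardClass(taxonomy, nm)]
}
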