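#' Item catalog for the 18-item Brief Psychiatric Rating Scale
#'
#' Returns the packaged catalog of the 18 BPRS items: short code, full item
#' name, and group label splitting the items into those mapping onto DSM-5
#' criteria for schizophrenia (\code{"DSM"}, 8 items) and those that do not
#' (\code{"non-DSM"}, 10 items). Item order follows the conventional
#' frequency-table ordering of the scale.
#'
#' @return a data frame of class \code{item_catalog} with columns
#'   \code{code}, \code{name}, \code{group}.
#' @export
#' @examples
#' cat <- bprs_catalog()
#' table(cat$group)
bprs_catalog <- function() {
  cat <- data.frame(
    code = c("SOM", "ANX", "EMO", "CON", "GUI", "TEN", "MAN", "GRA", "DEP",
             "HOS", "SUS", "HAL", "MOT", "UNC", "THO", "BLU", "EXC", "DIS"),
    name = c("Somatic concern", "Anxiety", "Emotional withdrawal",
             "Conceptual disorganization", "Guilt feelings", "Tension",
             "Mannerism and posturing", "Grandiosity", "Depressive mood",
             "Hostility", "Suspiciousness", "Hallucinatory behavior",
             "Motor retardation", "Uncooperativeness",
             "Unusual thought content", "Blunted affect", "Excitement",
             "Disorientation"),
    stringsAsFactors = FALSE
  )
  dsm <- c("EMO", "CON", "MAN", "SUS", "HAL", "MOT", "THO", "BLU")
  cat$group <- ifelse(cat$code %in% dsm, "DSM", "non-DSM")
  validate_catalog(cat)
}

#' Read an item catalog from JSON
#'
#' The JSON schema is an array of objects with fields \code{code},
#' \code{name}, \code{group}; \code{group} must take exactly two distinct
#' values across items.
#'
#' @param path path to a JSON file
#' @return an \code{item_catalog} data frame
#' @export
read_item_catalog <- function(path) {
  cat <- jsonlite::fromJSON(path)
  if (!all(c("code", "name", "group") %in% names(cat))) {
    stop("catalog JSON must provide fields code, name, group")
  }
  validate_catalog(cat[, c("code", "name", "group")])
}

validate_catalog <- function(cat) {
  if (anyDuplicated(cat$code)) {
    stop("duplicate item codes in catalog: ",
         paste(unique(cat$code[duplicated(cat$code)]), collapse = ", "))
  }
  if (length(unique(cat$group)) != 2) {
    stop("catalog must define exactly two item groups")
  }
  class(cat) <- c("item_catalog", "data.frame")
  cat
}

#' Write an item catalog as JSON
#' @param catalog an \code{item_catalog}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_item_catalog <- function(catalog, path) {
  jsonlite::write_json(as.data.frame(catalog), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}
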