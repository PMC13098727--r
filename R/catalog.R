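#' Construct a single variable-metadata record
#'
#' A catalog row describes one cohort variable: its measurement domain,
#' data type, ordinal scale bounds where relevant, the wave(s) it is
#' measured in, and whether it is an upstream modifiable determinant
#' (eligible for what-if perturbation) as opposed to a fixed attribute,
#' administrative artifact, or downstream proxy.
#'
#' @param name Unique variable identifier.
#' @param label Human-readable label (free text, used for semantic retrieval).
#' @param domain One of `"biological"`, `"behavioral"`, `"psychosocial"`,
#'   `"socioeconomic"`, `"administrative"`.
#' @param dtype One of `"continuous"`, `"ordinal"`, `"binary"`, `"categorical"`.
#' @param scale_min,scale_max Scale bounds. Required for ordinal variables
#'   (with `scale_min < scale_max`); optional plausibility bounds otherwise.
#' @param wave One of `"W2"`, `"W3"`, `"both"`.
#' @param modifiable Logical; `TRUE` only for upstream modifiable determinants.
#'   Administrative variables are always forced to `FALSE`.
#' @param proxy Logical; `TRUE` marks downstream proxy variables (e.g.
#'   medication checklists) that are predictive but not actionable.
#' @return A one-row data frame suitable for [variable_catalog()].
#' @export
variable_metadata <- function(name, label = name, domain, dtype,
                              scale_min = NA_real_, scale_max = NA_real_,
                              wave = "both", modifiable = FALSE,
                              proxy = FALSE) {
  domain <- match.arg(domain, c("biological", "behavioral", "psychosocial",
                                "socioeconomic", "administrative"))
  dtype <- match.arg(dtype, c("continuous", "ordinal", "binary", "categorical"))
  wave <- match.arg(wave, c("both", "W2", "W3"))
  if (domain == "administrative") modifiable <- FALSE
  if (dtype == "ordinal") {
    if (is.na(scale_min) || is.na(scale_max) || !(scale_min < scale_max)) {
      stop("ordinal variable '", name, "' requires scale_min < scale_max")
    }
  }
  data.frame(name = as.character(name), label = as.character(label),
             domain = domain, dtype = dtype,
             scale_min = as.numeric(scale_min), scale_max = as.numeric(scale_max),
             wave = wave, modifiable = isTRUE(modifiable),
             proxy = isTRUE(proxy), stringsAsFactors = FALSE)
}

#' Assemble and validate a variable catalog
#'
#' @param ... One-row data frames from [variable_metadata()], or data frames
#'   of such rows.
#' @return A `variable_catalog` data frame.
#' @export
variable_catalog <- function(...) {
  cat <- do.call(rbind, list(...))
  validate_catalog(cat)
}

#' @keywords internal
validate_catalog <- function(cat) {
  stopifnot(is.data.frame(cat))
  needed <- c("name", "label", "domain", "dtype", "scale_min", "scale_max",
              "wave", "modifiable")
  miss <- setdiff(needed, names(cat))
  if (length(miss)) stop("catalog missing columns: ", paste(miss, collapse = ", "))
  if (!"proxy" %in% names(cat)) cat$proxy <- FALSE
  if (anyDuplicated(cat$name)) {
    stop("duplicate variable names in catalog: ",
         paste(unique(cat$name[duplicated(cat$name)]), collapse = ", "))
  }
  ord <- cat$dtype == "ordinal"
  if (any(ord & !(cat$scale_min < cat$scale_max))) {
    stop("ordinal variables must have scale_min < scale_max")
  }
  bad <- cat$domain == "administrative" & cat$modifiable
  if (any(bad)) stop("administrative variables must be modifiable = FALSE: ",
                     paste(cat$name[bad], collapse = ", "))
  rownames(cat) <- NULL
  class(cat) <- c("variable_catalog", "data.frame")
  cat
}

#' @keywords internal
catalog_row <- function(catalog, name) {
  i <- match(name, catalog$name)
  if (is.na(i)) stop("variable '", name, "' not found in catalog")
  catalog[i, , drop = FALSE]
}
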