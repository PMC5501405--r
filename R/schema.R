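#' Define a single choice-experiment attribute
#'
#' An attribute is either categorical (a small set of labelled levels, one of
#' which is the reference against which marginal utilities are estimated) or
#' continuous (numeric values, here monthly out-of-pocket cost increments in
#' euro).
#'
#' @param name Character scalar, attribute label.
#' @param levels For `kind = "categorical"`, a character vector of at least two
#'   distinct level labels; for `kind = "continuous"`, a numeric vector of at
#'   least two distinct values (EUR/month increments).
#' @param kind `"categorical"` or `"continuous"`.
#' @param reference_level Categorical attributes only: the level coded as zero.
#'   Defaults to the last level.
#' @return An object of class `dce_attribute`.
#' @export
attribute_spec <- function(name, levels, kind = c("categorical", "continuous"),
                           reference_level = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("attribute `name` must be a non-empty string", call. = FALSE)
  }
  if (length(levels) < 2L) {
    stop("attribute '", name, "' needs at least 2 levels", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop("attribute '", name, "' has duplicated levels", call. = FALSE)
  }
  if (kind == "categorical") {
    levels <- as.character(levels)
    if (is.null(reference_level)) reference_level <- levels[length(levels)]
    if (!reference_level %in% levels) {
      stop("reference_level '", reference_level, "' is not a level of '",
           name, "'", call. = FALSE)
    }
  } else {
    levels <- as.numeric(levels)
    if (anyNA(levels)) stop("continuous levels must be numeric", call. = FALSE)
    reference_level <- NULL
  }
  structure(list(name = name, kind = kind, levels = levels,
                 reference_level = reference_level),
            class = "dce_attribute")
}

#' Assemble an attribute schema
#'
#' @param ... `dce_attribute` objects (or a single list of them).
#' @return An object of class `dce_schema`: a named list of attributes.
#' @export
attribute_schema <- function(...) {
  attrs <- list(...)
  if (length(attrs) == 1L && !inherits(attrs[[1L]], "dce_attribute")) {
    attrs <- attrs[[1L]]
  }
  if (length(attrs) == 0L) stop("empty attribute list", call. = FALSE)
  ok <- vapply(attrs, inherits, logical(1), "dce_attribute")
  if (!all(ok)) stop("all arguments must be attribute_spec() objects", call. = FALSE)
  nm <- vapply(attrs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicated attribute names", call. = FALSE)
  names(attrs) <- nm
  structure(attrs, class = "dce_schema")
}

#' The seven-attribute inhaler schema
#'
#' Six device attributes (ease of use, dose-counter accuracy, dose
#' confirmation by lactose taste, mouthpiece hygiene, handling flexibility,
#' usability during breathing difficulties) plus a continuous monthly cost
#' attribute with increments of 0, 3, 6 and 10 EUR/month over the current
#' level of expenditure. Reference levels are chosen so that every estimated
#' coefficient is the utility of an improvement (or a labelled alternative
#' state) relative to the least-featured device.
#'
#' @return A `dce_schema` with 7 attributes (level counts 3,2,2,3,2,2,4).
#' @export
inhaler_schema <- function() {
  attribute_schema(
    attribute_spec("ease_of_use",
                   c("1 step", "2 to 3 steps", "More than 4 steps"),
                   reference_level = "More than 4 steps"),
    attribute_spec("dose_counter", c("Yes", "No"), reference_level = "No"),
    attribute_spec("dose_confirmation",
                   c("Taste of lactose", "No taste of lactose"),
                   reference_level = "No taste of lactose"),
    attribute_spec("hygiene",
                   c("Mouthpiece can be replaced", "Mouthpiece can be washed",
                     "Cleaned with a dry cloth"),
                   reference_level = "Cleaned with a dry cloth"),
    attribute_spec("flexibility", c("Any position", "Certain position"),
                   reference_level = "Certain position"),
    attribute_spec("breathing_difficulties", c("Yes", "No"),
                   reference_level = "No"),
    attribute_spec("cost", c(0, 3, 6, 10), kind = "continuous")
  )
}

#' @export
print.dce_schema <- function(x, ...) {
  cat("DCE attribute schema (", length(x), " attributes)\n", sep = "")
  for (a in x) {
    if (a$kind == "categorical") {
      cat(sprintf("  %-24s %s [ref: %s]\n", a$name,
                  paste(a$levels, collapse = " | "), a$reference_level))
    } else {
      cat(sprintf("  %-24s continuous: %s EUR/month\n", a$name,
                  paste(a$levels, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Read / write an attribute schema as JSON
#'
#' @param path File path.
#' @return `read_schema()` returns a `dce_schema`.
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  attrs <- lapply(seq_len(nrow(raw$attributes)), function(i) {
    r <- raw$attributes[i, ]
    attribute_spec(r$name, unlist(r$levels), kind = r$kind,
                   reference_level = if (identical(r$kind, "categorical"))
                     r$reference_level else NULL)
  })
  attribute_schema(attrs)
}

#' @rdname read_schema
#' @param schema A `dce_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "dce_schema"))
  df <- data.frame(
    name = vapply(schema, `[[`, character(1), "name"),
    kind = vapply(schema, `[[`, character(1), "kind"),
    reference_level = vapply(schema, function(a)
      if (is.null(a$reference_level)) NA_character_ else a$reference_level,
      character(1)),
    stringsAsFactors = FALSE
  )
  df$levels <- I(lapply(schema, `[[`, "levels"))
  jsonlite::write_json(list(attributes = df), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Names of the coded model columns implied by a schema
#'
#' Dummy columns for each non-reference level of each categorical attribute
#' (in schema order), then each continuous attribute under its own name.
#' Column labels are `"<attribute>:<level>"` for dummies.
#'
#' @param schema A `dce_schema`.
#' @return Character vector of coded column names.
#' @export
schema_terms <- function(schema) {
  out <- character(0)
  for (a in schema) {
    if (a$kind == "categorical") {
      lv <- setdiff(a$levels, a$reference_level)
      out <- c(out, paste0(a$name, ":", lv))
    } else {
      out <- c(out, a$name)
    }
  }
  out
}

#' Code profiles into the design/dummy coding
#'
#' @param profiles A data.frame with one column per attribute (level labels for
#'   categorical attributes, numeric values for continuous ones) and one row
#'   per profile.
#' @param schema A `dce_schema`.
#' @param center_continuous Centre continuous columns on the mean of their
#'   level set (used for design construction so the cost column is orthogonal
#'   to the intercept-free dummy block).
#' @return Numeric matrix, rows aligned with `profiles`, columns
#'   `schema_terms(schema)`.
#' @export
code_profiles <- function(profiles, schema, center_continuous = FALSE) {
  stopifnot(is.data.frame(profiles))
  terms <- schema_terms(schema)
  X <- matrix(0, nrow(profiles), length(terms),
              dimnames = list(NULL, terms))
  for (a in schema) {
    if (!a$name %in% names(profiles)) {
      stop("profiles lack attribute column '", a$name, "'", call. = FALSE)
    }
    v <- profiles[[a$name]]
    if (a$kind == "categorical") {
      bad <- !v %in% a$levels
      if (any(bad)) {
        stop("unknown level '", v[which(bad)[1L]], "' for attribute '",
             a$name, "' (row ", which(bad)[1L], ")", call. = FALSE)
      }
      for (lv in setdiff(a$levels, a$reference_level)) {
        X[, paste0(a$name, ":", lv)] <- as.numeric(v == lv)
      }
    } else {
      v <- as.numeric(v)
      if (anyNA(v)) stop("non-numeric value for '", a$name, "'", call. = FALSE)
      X[, a$name] <- if (center_continuous) v - mean(a$levels) else v
    }
  }
  X
}

#' All attribute-level combinations of a schema
#'
#' The full factorial serves as the candidate profile set for the
#' D-efficiency search.
#'
#' @param schema A `dce_schema` (or list of `dce_attribute`).
#' @return data.frame with one row per profile, one column per attribute;
#'   `prod(level counts)` rows, all distinct.
#' @export
enumerate_full_factorial <- function(schema) {
  if (length(schema) == 0L) stop("empty attribute list", call. = FALSE)
  lv <- lapply(schema, `[[`, "levels")
  names(lv) <- vapply(schema, `[[`, character(1), "name")
  out <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
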