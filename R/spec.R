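#' Build a variable-type specification
#'
#' A type specification declares, for every variable column of a mixed table,
#' its measurement scale, an optional ordered list of category levels, and an
#' optional nonnegative Gower weight. It is stored as a tibble so it can be
#' created, filtered and joined with the usual dplyr verbs.
#'
#' @param variable Character vector of variable (column) names.
#' @param scale Character vector, one of `"quantitative"`, `"ordinal"`,
#'   `"nominal"`, `"binary"` per variable (recycled if length 1).
#' @param levels List of character vectors giving the category levels. Required
#'   (non-empty, unique, low to high) for ordinal variables; optional for
#'   nominal/binary, where undeclared levels are taken in order of first
#'   appearance in the data.
#' @param weight Nonnegative numeric weights used by [gower_dist()]; default 1.
#'
#' @return A tibble of class `mixed_spec` with columns `variable`, `scale`,
#'   `levels` (list-column) and `weight`.
#' @seealso [read_type_spec()], [read_mixed_table()]
#' @export
#' @examples
#' mixed_spec(
#'   variable = c("age", "grade", "subtype"),
#'   scale = c("quantitative", "ordinal", "nominal"),
#'   levels = list(NULL, c("I", "II", "III"), NULL)
#' )
mixed_spec <- function(variable, scale, levels = NULL, weight = 1) {
  variable <- as.character(variable)
  p <- length(variable)
  scale <- rep_len(as.character(scale), p)
  if (is.null(levels)) levels <- vector("list", p)
  if (!is.list(levels)) levels <- list(levels)
  levels <- rep_len(levels, p)
  levels <- lapply(levels, function(l) if (is.null(l)) NULL else as.character(l))
  weight <- rep_len(as.numeric(weight), p)
  spec <- tibble::tibble(
    variable = variable, scale = scale,
    levels = levels, weight = weight
  )
  class(spec) <- c("mixed_spec", class(spec))
  validate_mixed_spec(spec)
}

#' Coerce a data frame to a `mixed_spec`
#'
#' @param x A data frame with columns `variable` and `scale`, and optionally
#'   `levels` (list-column or comma-separated strings) and `weight`.
#' @return A validated [mixed_spec()] tibble.
#' @export
as_mixed_spec <- function(x) {
  if (inherits(x, "mixed_spec")) {
    return(validate_mixed_spec(x))
  }
  stopifnot(is.data.frame(x), all(c("variable", "scale") %in% names(x)))
  lev <- if ("levels" %in% names(x)) x$levels else NULL
  if (!is.null(lev) && !is.list(lev)) {
    lev <- lapply(as.character(lev), function(s) {
      if (is.na(s) || !nzchar(s)) NULL else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  }
  w <- if ("weight" %in% names(x)) {
    wn <- suppressWarnings(as.numeric(x$weight))
    ifelse(is.na(wn), 1, wn)
  } else {
    1
  }
  mixed_spec(x$variable, x$scale, lev, w)
}

mixed_scales <- c("quantitative", "ordinal", "nominal", "binary")

validate_mixed_spec <- function(spec) {
  bad <- setdiff(unique(spec$scale), mixed_scales)
  if (length(bad) > 0) {
    stop("unknown scale(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(spec$variable)) {
    stop("duplicate variable names in spec", call. = FALSE)
  }
  if (any(spec$weight < 0 | is.na(spec$weight))) {
    stop("weights must be nonnegative", call. = FALSE)
  }
  ord <- spec$scale == "ordinal"
  lev_ok <- vapply(
    spec$levels[ord],
    function(l) length(l) > 0 && !anyDuplicated(l),
    logical(1)
  )
  if (any(!lev_ok)) {
    stop(
      "ordinal variable(s) without non-empty unique levels: ",
      paste(spec$variable[ord][!lev_ok], collapse = ", "),
      call. = FALSE
    )
  }
  spec
}

#' Read a variable-type specification file
#'
#' The file is tab-separated with header columns `variable`, `scale`,
#' `levels`, `weight`. `levels` is a comma-separated list (low to high for
#' ordinal variables); empty fields fall back to defaults.
#'
#' @param path Path to the spec TSV.
#' @return A [mixed_spec()] tibble.
#' @export
read_type_spec <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  as_mixed_spec(x)
}

#' Read a delimited mixed-type data table
#'
#' Reads a CSV or TSV table whose first column holds unique sample identifiers
#' and whose remaining columns are the variables declared in `spec`. Cells are
#' coerced to the declared scale: quantitative columns to numeric (unparseable
#' cells become missing), ordinal columns to ordered factors with the declared
#' level order, nominal/binary columns to factors (undeclared level order =
#' order of first appearance). Missing tokens (by default the empty string and
#' `"NA"`) become `NA`.
#'
#' @param path Path to the data table (`.csv` uses comma, anything else tab).
#' @param spec A [mixed_spec()] or path to a spec file.
#' @param missing_tokens Character vector of cell values treated as missing
#'   (matched case-sensitively).
#' @return A tibble whose first column is the sample identifier and whose
#'   variable columns are coerced per `spec`.
#' @export
read_mixed_table <- function(path, spec, missing_tokens = c("", "NA")) {
  if (is.character(spec) && length(spec) == 1 && file.exists(spec)) {
    spec <- read_type_spec(spec)
  }
  spec <- as_mixed_spec(spec)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(
    path,
    delim = delim, na = character(),
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE
  )
  if (ncol(raw) < 2) stop("table needs a sample-ID column plus >= 1 variable", call. = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) stop("duplicate sample IDs in first column", call. = FALSE)
  vars <- raw[, -1, drop = FALSE]
  unknown <- setdiff(spec$variable, names(vars))
  if (length(unknown) > 0) {
    stop("spec lists variable(s) absent from table: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(names(vars), spec$variable)
  if (length(extra) > 0) {
    stop("table column(s) not in spec: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  out <- vars[, spec$variable, drop = FALSE]
  for (j in seq_len(nrow(spec))) {
    v <- out[[j]]
    v[v %in% missing_tokens] <- NA_character_
    out[[j]] <- coerce_cells(v, spec$scale[j], spec$levels[[j]], spec$variable[j])
  }
  dplyr::bind_cols(stats::setNames(tibble::tibble(ids), names(raw)[1]), out)
}

coerce_cells <- function(v, scale, levels, name) {
  if (scale == "quantitative") {
    num <- suppressWarnings(as.numeric(v))
    return(num)
  }
  obs <- unique(v[!is.na(v)])
  if (scale == "ordinal") {
    bad <- setdiff(obs, levels)
    if (length(bad) > 0) {
      stop(
        "ordinal variable '", name, "' has value(s) outside declared levels: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    return(factor(v, levels = levels, ordered = TRUE))
  }
  lev <- if (is.null(levels)) obs else union(levels, obs)
  if (scale == "binary" && length(obs) > 2) {
    stop("binary variable '", name, "' has ", length(obs), " observed categories",
      call. = FALSE
    )
  }
  factor(v, levels = lev)
}

#' Per-variable summary of a mixed table
#'
#' @param data A data frame of samples by variables (an identifier column is
#'   detected as any column absent from `spec`).
#' @param spec A [mixed_spec()] covering the variable columns.
#' @return A tibble with one row per variable: `variable`, `scale`,
#'   `n_missing`, `n_categories` (categorical scales), `range` (quantitative),
#'   and a `degenerate` flag (all missing, constant, or a binary variable with
#'   more than two observed categories is an error).
#' @export
summarize_variables <- function(data, spec) {
  cm <- compile_mixed(data, spec)
  purrr::map_dfr(cm$vars, function(v) {
    x <- v$x[!is.na(v$x)]
    quant <- v$scale == "quantitative"
    ncat <- if (quant) NA_integer_ else length(unique(x))
    rng <- if (quant && length(x) > 0) diff(range(x)) else NA_real_
    tibble::tibble(
      variable = v$name, scale = v$scale,
      n_missing = sum(is.na(v$x)),
      n_categories = ncat,
      range = rng,
      degenerate = length(unique(x)) < 2
    )
  })
}

# Canonical internal representation: per-variable values (numeric or factor),
# scale tag, weight. Detects at most one non-spec column as the sample ID.
# With spec = NULL every column is a variable and its scale is inferred.
compile_mixed <- function(data, spec = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(spec)) spec <- infer_spec(data)
  spec <- as_mixed_spec(spec)
  id_cols <- setdiff(names(data), spec$variable)
  if (length(id_cols) > 1) {
    stop("columns not covered by spec: ", paste(id_cols, collapse = ", "), call. = FALSE)
  }
  ids <- if (length(id_cols) == 1) {
    as.character(data[[id_cols]])
  } else if (tibble::has_rownames(as.data.frame(data))) {
    rownames(as.data.frame(data))
  } else {
    as.character(seq_len(nrow(data)))
  }
  if (anyDuplicated(ids)) stop("duplicate sample IDs", call. = FALSE)
  missing_vars <- setdiff(spec$variable, names(data))
  if (length(missing_vars) > 0) {
    stop("spec lists variable(s) absent from data: ",
      paste(missing_vars, collapse = ", "),
      call. = FALSE
    )
  }
  vars <- purrr::pmap(spec, function(variable, scale, levels, weight) {
    x <- data[[variable]]
    if (scale == "quantitative") {
      x <- as.numeric(x)
    } else if (scale == "ordinal") {
      if (is.ordered(x) && is.null(levels)) levels <- base::levels(x)
      x <- coerce_cells(as.character(x), "ordinal", levels, variable)
    } else {
      if (is.factor(x) && is.null(levels)) levels <- base::levels(x)
      x <- coerce_cells(as.character(x), scale, levels, variable)
    }
    list(name = variable, x = x, scale = scale, weight = weight)
  })
  names(vars) <- spec$variable
  list(ids = ids, vars = vars, n = nrow(data), p = nrow(spec), spec = spec)
}

# Fallback scale inference from column classes, used when no spec is given:
# numeric -> quantitative, ordered factor -> ordinal, 2-level factor/character
# -> binary, otherwise nominal.
infer_spec <- function(data) {
  cols <- names(data)
  scales <- vapply(data, function(x) {
    if (is.numeric(x)) {
      "quantitative"
    } else if (is.ordered(x)) {
      "ordinal"
    } else if (length(unique(stats::na.omit(as.character(x)))) == 2) {
      "binary"
    } else {
      "nominal"
    }
  }, character(1))
  levels <- lapply(data, function(x) if (is.factor(x)) base::levels(x) else NULL)
  mixed_spec(cols, scales, levels)
}
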