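## Measurement tables: reading, validation, derived structural totals,
## diagnostic ratios and grouped descriptive statistics.

category_columns <- c("locomotor_mode", "habitat", "phylo_group")

#' Read and validate a per-species measurement table
#'
#' Reads a delimited text file (comma default, tab accepted) with a header
#' row of measurement abbreviations, validates types, uniqueness of
#' `species_id`, positivity of all length measurements, the iliac-angle
#' range, and that categorical labels are drawn from the declared levels.
#'
#' @param source Path to a delimited file, or a `data.frame` already in
#'   memory (validated the same way).
#' @param sep Field separator; `NULL` (default) tries comma then tab.
#' @param required Character vector of measurement columns that must be
#'   present and complete. Defaults to the full 16-variable set.
#' @param on_missing `"error"` (default) fails listing offending species;
#'   `"drop"` removes incomplete rows with a message naming them.
#' @return A validated `data.frame` of class `measurement_table`.
#'   Categorical columns are factors with the declared level order;
#'   secondary-label columns (`locomotor_mode2`, `habitat2`) and flag
#'   columns (`proxy_mode`, `side_used`, `ossification_note`) pass through
#'   when present.
#' @seealso [derive_structural()], [mosimann_shape()], [compute_ratios()]
#' @export
read_measurements <- function(source, sep = NULL,
                              required = measurement_variables("full"),
                              on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  if (is.character(source)) {
    if (!file.exists(source)) stop("measurement file not found: ", source)
    if (is.null(sep)) {
      header <- readLines(source, n = 1L)
      sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    }
    tab <- utils::read.table(source, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             fileEncoding = "UTF-8")
  } else {
    tab <- as.data.frame(source, stringsAsFactors = FALSE)
  }
  validate_measurements(tab, required = required, on_missing = on_missing)
}

validate_measurements <- function(tab, required, on_missing = "error") {
  if (!"species_id" %in% names(tab)) stop("column 'species_id' is required")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- tab$species_id[duplicated(tab$species_id)]
  if (length(dup) > 0L) {
    stop("duplicate species_id: ", paste(unique(dup), collapse = ", "))
  }

  num_cols <- intersect(required, names(tab))
  incomplete <- rowSums(is.na(tab[, num_cols, drop = FALSE])) > 0L
  if (any(incomplete)) {
    ids <- tab$species_id[incomplete]
    if (on_missing == "error") {
      stop("missing required values for species: ", paste(ids, collapse = ", "))
    }
    message("dropping ", length(ids), " incomplete row(s): ",
            paste(ids, collapse = ", "))
    tab <- tab[!incomplete, , drop = FALSE]
  }

  lengths_cols <- setdiff(num_cols, angle_variables)
  for (cl in lengths_cols) {
    v <- tab[[cl]]
    if (!is.numeric(v)) stop("column '", cl, "' is not numeric")
    bad <- which(v <= 0)
    if (length(bad) > 0L) {
      stop("non-positive measurement in column '", cl, "' for species: ",
           paste(tab$species_id[bad], collapse = ", "))
    }
  }
  if ("iliac_angle" %in% names(tab)) {
    th <- tab$iliac_angle
    bad <- which(!is.na(th) & (th <= 0 | th >= 90))
    if (length(bad) > 0L) {
      stop("iliac_angle outside (0, 90) degrees for species: ",
           paste(tab$species_id[bad], collapse = ", "))
    }
  }

  levels_map <- category_levels()
  for (cl in intersect(category_columns, names(tab))) {
    vals <- as.character(tab[[cl]])
    ok_levels <- levels_map[[cl]]
    unknown <- setdiff(unique(vals[!is.na(vals)]), ok_levels)
    if (length(unknown) > 0L) {
      stop("unknown ", cl, " level(s): ", paste(unknown, collapse = ", "),
           "; allowed: ", paste(ok_levels, collapse = ", "))
    }
    tab[[cl]] <- factor(vals, levels = ok_levels)
  }

  rownames(tab) <- tab$species_id
  class(tab) <- c("measurement_table", "data.frame")
  attr(tab, "variable_set") <- intersect(names(tab), c(required, "ESD"))
  tab
}

#' Default composition map for structural totals
#'
#' Component lists for snout-vent length (SVL), hindlimb length (HL) and
#' forelimb length (FL). The axial composition of SVL is configurable:
#' the pelvis is excluded by default and can be added with
#' `include_pelv = TRUE`.
#'
#' @param include_pelv Add the pelvis column to the SVL total.
#' @return Named list mapping each total to its component column names.
#' @export
default_composition <- function(include_pelv = FALSE) {
  svl <- c("skull", "vert")
  if (include_pelv) svl <- c(svl, "pelv")
  list(
    SVL = svl,
    HL = c("fem", "tib", "calc", "foot"),
    FL = c("hum", "rad", "hand")
  )
}

#' Derive the structural (9-variable) measurement table
#'
#' Sums individual skeletal segments into body and limb totals according to
#' a composition map and returns the structural variable set (SVL, sacr_w,
#' ilium, uro, iliac_angle, HL, fem_w, FL, hum_w). Variables not consumed
#' by a total pass through unchanged; component columns are dropped from
#' the active variable set.
#'
#' @param table A `measurement_table` with the full variable set.
#' @param composition Named list mapping total names to component columns;
#'   see [default_composition()].
#' @return A `measurement_table` whose active variable set is the 9
#'   structural variables (attribute `variable_set`); category and id
#'   columns, and uninvolved extra columns such as `ESD`, are retained.
#' @export
derive_structural <- function(table, composition = default_composition()) {
  for (total in names(composition)) {
    comps <- composition[[total]]
    missing_comp <- setdiff(comps, names(table))
    if (length(missing_comp) > 0L) {
      stop("composition for '", total, "' references missing column(s): ",
           paste(missing_comp, collapse = ", "))
    }
    table[[total]] <- rowSums(as.matrix(table[comps]))
  }
  consumed <- unique(unlist(composition))
  keep_meta <- intersect(
    c("species_id", "family", category_columns,
      "locomotor_mode2", "habitat2", "proxy_mode",
      "side_used", "ossification_note"),
    names(table)
  )
  vars <- intersect(structural_variables, names(table))
  extra <- setdiff(names(table), c(keep_meta, vars, consumed, full_variables))
  out <- table[c(keep_meta, vars, extra)]
  class(out) <- c("measurement_table", "data.frame")
  attr(out, "variable_set") <- vars
  attr(out, "composition") <- composition
  out
}

#' Diagnostic limb and body ratios
#'
#' Computes the ten scale-free ratios used for descriptive comparison of
#' relative segment and limb lengths: HL/FL, HL/SVL, ESD/HL, fem/HL,
#' tib/HL, calc/HL, foot/HL, tib/fem, fem_w/fem, hum_w/hum. Ratios are
#' computed per specimen from raw measurements (never from group means and
#' never size-corrected first, since ratios are already dimensionless).
#' Structural totals are derived on the fly when absent.
#'
#' @param table A `measurement_table` holding the full variable set (plus
#'   `ESD`).
#' @param composition Composition map used to derive missing totals.
#' @return `data.frame` with `species_id` and one column per ratio (named
#'   `"HL/FL"` etc.).
#' @export
compute_ratios <- function(table, composition = default_composition()) {
  ratio_defs <- list(
    "HL/FL" = c("HL", "FL"), "HL/SVL" = c("HL", "SVL"),
    "ESD/HL" = c("ESD", "HL"), "fem/HL" = c("fem", "HL"),
    "tib/HL" = c("tib", "HL"), "calc/HL" = c("calc", "HL"),
    "foot/HL" = c("foot", "HL"), "tib/fem" = c("tib", "fem"),
    "fem_w/fem" = c("fem_w", "fem"), "hum_w/hum" = c("hum_w", "hum")
  )
  totals_needed <- setdiff(c("HL", "FL", "SVL"), names(table))
  for (total in totals_needed) {
    comps <- composition[[total]]
    missing_comp <- setdiff(comps, names(table))
    if (length(missing_comp) > 0L) {
      stop("cannot derive '", total, "': missing column(s) ",
           paste(missing_comp, collapse = ", "))
    }
    table[[total]] <- rowSums(as.matrix(table[comps]))
  }
  out <- data.frame(species_id = table$species_id,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (rn in names(ratio_defs)) {
    parts <- ratio_defs[[rn]]
    missing_part <- setdiff(parts, names(table))
    if (length(missing_part) > 0L) {
      stop("ratio '", rn, "' needs missing column(s): ",
           paste(missing_part, collapse = ", "))
    }
    out[[rn]] <- table[[parts[1]]] / table[[parts[2]]]
  }
  rownames(out) <- out$species_id
  out
}

#' Grouped descriptive statistics
#'
#' Per-group, per-variable mean and standard error (sd/sqrt(n)), with flags
#' marking the group holding the highest and lowest mean of each variable.
#' Ties are broken in favour of the first group in the declared level
#' order. Rows whose group label is listed in `exclude` are removed before
#' summarising (the 'Neobatrachia' label is excluded this way when
#' summarising by clade).
#'
#' @param values Numeric `data.frame` or matrix, one row per species.
#' @param groups Factor or character vector of group labels, one per row.
#' @param level_order Optional explicit level order (defaults to factor
#'   levels or order of appearance).
#' @param exclude Labels to drop before summarising.
#' @return Object of class `group_summary`: a long `data.frame` with
#'   columns `group`, `variable`, `n`, `mean`, `se`, `is_max`, `is_min`,
#'   plus attributes `n_total` (rows summarised) and `level_order`.
#' @export
group_summary <- function(values, groups, level_order = NULL,
                          exclude = character(0)) {
  values <- as.data.frame(values)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(values))
  keep <- !(groups %in% exclude) & !is.na(groups)
  values <- values[keep, , drop = FALSE]
  groups <- groups[keep]
  if (is.null(level_order)) {
    level_order <- unique(groups)
  } else {
    level_order <- setdiff(level_order, exclude)
  }
  counts <- table(factor(groups, levels = level_order))
  if (any(counts == 0L)) {
    stop("group(s) with no members after exclusions: ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  }
  num_cols <- names(values)[vapply(values, is.numeric, logical(1))]
  rows <- list()
  for (v in num_cols) {
    m <- tapply(values[[v]], factor(groups, levels = level_order), mean)
    s <- tapply(values[[v]], factor(groups, levels = level_order),
                function(x) stats::sd(x) / sqrt(length(x)))
    s[is.na(s)] <- 0 # single observation: sd undefined, SE reported as 0
    i_max <- which.max(m) # which.max takes the first maximum: declared order
    i_min <- which.min(m)
    rows[[v]] <- data.frame(
      group = level_order, variable = v,
      n = as.integer(counts[level_order]),
      mean = as.numeric(m), se = as.numeric(s),
      is_max = seq_along(level_order) == i_max,
      is_min = seq_along(level_order) == i_min,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_total") <- length(groups)
  attr(out, "level_order") <- level_order
  class(out) <- c("group_summary", "data.frame")
  out
}

#' @export
print.group_summary <- function(x, digits = 3, ...) {
  cat("Grouped descriptive statistics (mean ± SE)\n")
  lev <- attr(x, "level_order")
  cnt <- x$n[match(lev, x$group)]
  cat("Groups:", paste0(lev, " (", cnt, ")", collapse = ", "), "\n\n")
  wide <- stats::reshape(
    data.frame(group = x$group, variable = x$variable,
               cell = paste0(formatC(x$mean, digits = digits, format = "fg"),
                             " ± ",
                             formatC(x$se, digits = digits, format = "fg"))),
    idvar = "variable", timevar = "group", direction = "wide"
  )
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Serialise a group summary as a structured report
#'
#' @param x A `group_summary`.
#' @param path Optional file to write the JSON document to.
#' @return JSON string (invisibly when `path` given).
#' @export
group_summary_report <- function(x, path = NULL) {
  payload <- list(
    level_order = attr(x, "level_order"),
    n_total = attr(x, "n_total"),
    rows = as.data.frame(unclass(x), stringsAsFactors = FALSE)
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
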