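# Reading and writing model files.
#
# Two dialects:
#  * JSON: {"variables":[{"name":"P","levels":3},...],
#           "rules":{"P":"<expression>" or "table:NAME"},
#           "tables":{NAME: [..]},          # full-domain, variable 1 slowest
#           "propensities":{"P":{"up":.9,"down":.9}}}
#  * truth-table TSV: '#'-prefixed propensity header lines, then a header row
#    of variable names plus one f_<var> target column per variable, one row
#    per state in lexicographic order.
# Probabilities are always serialised as decimals.

#' Parse a model from text
#'
#' @param text model-file content as a single string or character vector of
#'   lines.
#' @param dialect `"json"` or `"tsv"`.
#' @return a validated [sdds_model()]; expression rules are expanded and
#'   cached as truth tables.
#' @seealso [write_model()], [read_model_file()]
#' @export
parse_model <- function(text, dialect = c("json", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") parse_model_json(text) else parse_model_tsv(text)
}

parse_model_json <- function(text) {
  text <- paste(text, collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    sdds_stop("sdds_parse_error", "malformed JSON: %s",
                              conditionMessage(e)))
  for (field in c("variables", "rules", "propensities"))
    if (is.null(doc[[field]]))
      sdds_stop("sdds_parse_error", "missing field '%s'", field)
  vars <- vapply(doc$variables, function(v) {
    if (is.null(v$name) || is.null(v$levels))
      sdds_stop("sdds_parse_error", "each variable needs 'name' and 'levels'")
    as.integer(v$levels)
  }, integer(1))
  names(vars) <- vapply(doc$variables, function(v) as.character(v$name),
                        character(1))
  rules <- lapply(doc$rules, function(r) as.character(r))
  # resolve "table:NAME" references
  rules <- lapply(rules, function(r) {
    if (startsWith(r, "table:")) {
      nm <- sub("^table:", "", r)
      tab <- doc$tables[[nm]]
      if (is.null(tab))
        sdds_stop("sdds_parse_error", "rule references missing table '%s'", nm)
      as.numeric(unlist(tab))
    } else r
  })
  props <- lapply(doc$propensities, function(p) {
    c(up = if (is.null(p$up)) NA_real_ else as.numeric(p$up),
      down = if (is.null(p$down)) NA_real_ else as.numeric(p$down))
  })
  missing_p <- setdiff(names(vars), names(props))
  if (length(missing_p))
    sdds_stop("sdds_validation_error", "missing propensity for variable '%s'",
              missing_p[1L])
  sdds_model(vars, rules, props)
}

parse_model_tsv <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  prop_lines <- grep("^#\\s*propensity\\b", lines, value = TRUE)
  body <- lines[!startsWith(trimws(lines), "#")]
  if (length(body) < 2L)
    sdds_stop("sdds_parse_error", "truth-table TSV needs a header and at least one state row")
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1]]
  target_cols <- grep("^f_", header)
  var_cols <- setdiff(seq_along(header), target_cols)
  var_names <- header[var_cols]
  if (!identical(sub("^f_", "", header[target_cols]), var_names))
    sdds_stop("sdds_parse_error",
              "target columns must be f_<var> in the variable order of the state columns")
  cells <- lapply(body[-1L], function(l) {
    v <- suppressWarnings(as.integer(strsplit(l, "\t", fixed = TRUE)[[1]]))
    if (length(v) != length(header) || any(is.na(v)))
      sdds_stop("sdds_parse_error", "bad state row: '%s'", l)
    v
  })
  m <- do.call(rbind, cells)
  states <- m[, var_cols, drop = FALSE]
  targets <- m[, target_cols, drop = FALSE]
  cards <- apply(states, 2L, max) + 1L
  names(cards) <- var_names
  expect <- enumerate_states(cards)
  if (nrow(states) != nrow(expect) || any(states != expect))
    sdds_stop("sdds_parse_error",
              "state rows must enumerate the whole space in lexicographic order")
  props <- list()
  for (pl in prop_lines) {
    parts <- strsplit(trimws(sub("^#\\s*propensity\\b", "", pl)), "\\s+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) != 3L)
      sdds_stop("sdds_parse_error", "propensity line must be '# propensity VAR up down'")
    props[[parts[1L]]] <- c(up = as.numeric(parts[2L]), down = as.numeric(parts[3L]))
  }
  missing_p <- setdiff(var_names, names(props))
  if (length(missing_p))
    sdds_stop("sdds_validation_error", "missing propensity for variable '%s'",
              missing_p[1L])
  rules <- lapply(seq_along(var_names), function(j) as.numeric(targets[, j]))
  names(rules) <- var_names
  sdds_model(cards, rules, props)
}

#' Serialise a model to text
#'
#' Writing then parsing gives back a model with identical truth tables and
#' propensities (the canonical expanded form round-trips; expression strings
#' are carried along in the JSON dialect for readability).
#'
#' @param model an `sdds_model`.
#' @param dialect `"json"` or `"tsv"`.
#' @return a single string of model-file content.
#' @export
write_model <- function(model, dialect = c("json", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") write_model_json(model) else write_model_tsv(model)
}

write_model_json <- function(model) {
  nm <- model$variables$name
  doc <- list(
    variables = lapply(seq_len(model$n), function(j)
      list(name = nm[j], levels = model$cardinalities[[j]])),
    rules = setNames(as.list(paste0("table:", nm)), nm),
    tables = setNames(lapply(seq_len(model$n), function(j)
      as.integer(model$table[, j])), nm),
    propensities = setNames(lapply(seq_len(model$n), function(j)
      list(up = model$propensities[j, "up"],
           down = model$propensities[j, "down"])), nm)
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE))
}

write_model_tsv <- function(model) {
  nm <- model$variables$name
  prop_lines <- sprintf("# propensity %s %.17g %.17g", nm,
                        model$propensities[, "up"],
                        model$propensities[, "down"])
  header <- paste(c(nm, paste0("f_", nm)), collapse = "\t")
  rows <- apply(cbind(model$states, model$table), 1L, paste, collapse = "\t")
  paste(c(prop_lines, header, rows), collapse = "\n")
}

#' Read / write model files
#'
#' The dialect is taken from the file extension (`.json` vs `.tsv`/`.txt`)
#' unless given explicitly.
#'
#' @param path file path.
#' @param dialect `"json"`, `"tsv"`, or `NULL` to infer from the extension.
#' @return `read_model_file()`: an `sdds_model`; `write_model_file()`: the
#'   path, invisibly.
#' @export
read_model_file <- function(path, dialect = NULL) {
  if (is.null(dialect))
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (!file.exists(path))
    sdds_stop("sdds_parse_error", "model file '%s' does not exist", path)
  parse_model(readLines(path, warn = FALSE), dialect)
}

#' @rdname read_model_file
#' @param model an `sdds_model`.
#' @export
write_model_file <- function(model, path, dialect = NULL) {
  if (is.null(dialect))
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  writeLines(write_model(model, dialect), path)
  invisible(path)
}
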