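## A minimal TOML reader covering the configuration dialect this package
## uses: tables, arrays of tables, bare/quoted keys, strings, numbers,
## booleans and one-level arrays. Parse errors carry the offending line
## number. (No installed R package provides TOML parsing, so the subset
## needed for the configuration surface is implemented here.)

#' Parse TOML text
#'
#' Supports the subset of TOML used by the experiment configuration files:
#' `[table]` and nested `[table.sub]` headers, `[[array-of-tables]]`,
#' `key = value` pairs with string, numeric, boolean and flat array values,
#' and `#` comments.
#'
#' @param text A single string, or a character vector of lines.
#' @return A nested named list.
#' @examples
#' cfg <- parse_toml("[schedule]\nlength = \"16h\"\nseed = 1")
#' cfg$schedule$length
#' @export
parse_toml <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  root <- list()
  path <- character(0)       # current table path
  aot_last <- FALSE          # is the current path an array-of-tables element?
  perr <- function(i, msg) stop(sprintf("TOML parse error at line %d: %s", i, msg), call. = FALSE)

  strip_comment <- function(s) {
    out <- character(1); inq <- FALSE
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (k in seq_along(chars)) {
      ch <- chars[k]
      if (ch == '"') inq <- !inq
      if (ch == "#" && !inq) return(substr(s, 1, k - 1))
    }
    s
  }

  as_key <- function(lst, nm) {
    if (grepl("^[0-9]+$", nm)) as.integer(nm) else nm
  }
  get_at <- function(lst, p) {
    for (nm in p) {
      lst <- lst[[as_key(lst, nm)]]
      if (is.null(lst)) return(NULL)
    }
    lst
  }
  set_at <- function(lst, p, value) {
    if (length(p) == 0L) return(value)
    k <- as_key(lst, p[1])
    lst[[k]] <- set_at(lst[[k]] %||% list(), p[-1], value)
    lst
  }

  parse_value <- function(v, i) {
    v <- trimws(v)
    if (v == "") perr(i, "missing value")
    if (grepl("^\\[", v)) {
      inner <- sub("^\\[", "", sub("\\]$", "", v))
      if (!grepl("\\]$", v)) perr(i, "unterminated array")
      if (trimws(inner) == "") return(list())
      parts <- strsplit(inner, ",")[[1]]
      vals <- lapply(parts, parse_value, i = i)
      if (all(vapply(vals, is.numeric, TRUE))) return(unlist(vals))
      if (all(vapply(vals, is.character, TRUE))) return(unlist(vals))
      return(vals)
    }
    if (grepl('^".*"$', v)) return(gsub('\\\\(["\\\\])', "\\1", substr(v, 2, nchar(v) - 1)))
    if (grepl("^'.*'$", v)) return(substr(v, 2, nchar(v) - 1))
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(gsub("_", "", v)))
    if (!is.na(num)) return(num)
    perr(i, sprintf("cannot parse value '%s'", v))
  }

  split_path <- function(s) {
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    trimws(gsub('^"|"$', "", trimws(parts)))
  }

  for (i in seq_along(lines)) {
    line <- trimws(strip_comment(lines[i]))
    if (line == "") next
    if (grepl("^\\[\\[", line)) {
      if (!grepl("\\]\\]$", line)) perr(i, "malformed array-of-tables header")
      p <- split_path(sub("^\\[\\[", "", sub("\\]\\]$", "", line)))
      cur <- get_at(root, p) %||% list()
      cur[[length(cur) + 1L]] <- list()
      root <- set_at(root, p, cur)
      path <- c(p, as.character(length(cur)))
      aot_last <- TRUE
      next
    }
    if (grepl("^\\[", line)) {
      if (!grepl("\\]$", line)) perr(i, "malformed table header")
      path <- split_path(sub("^\\[", "", sub("\\]$", "", line)))
      if (any(path == "")) perr(i, "empty table name")
      root <- set_at(root, path, get_at(root, path) %||% list())
      aot_last <- FALSE
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) perr(i, "expected 'key = value'")
    key <- trimws(gsub('^"|"$', "", trimws(substr(line, 1, eq - 1))))
    if (key == "") perr(i, "empty key")
    val <- parse_value(substr(line, eq + 1, nchar(line)), i)
    root <- set_at(root, c(path, key), val)
  }
  root
}

## Serialize a flat named list (scalars and numeric/character vectors) as a
## TOML table body. Used by round-trip tests and fixture emission.
toml_table <- function(name, kv) {
  fmt <- function(v) {
    if (is.character(v) && length(v) == 1L) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else if (length(v) > 1L) sprintf("[%s]", paste(vapply(v, function(z) fmt(z), ""), collapse = ", "))
    else format(v, scientific = FALSE)
  }
  c(sprintf("[%s]", name),
    vapply(names(kv), function(k) sprintf("%s = %s", k, fmt(kv[[k]])), ""))
}
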