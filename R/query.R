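#' Parse a Boolean key-value filter query
#'
#' The evidence-table query language: comparisons `KEY op VALUE` with
#' `op` in `=`, `!=`, `<`, `<=`, `>`, `>=`, combined with `&` and `|` and
#' parentheses; `&` binds tighter than `|`. Keys are case-insensitive and
#' resolve to evidence-table columns (`INFO_`-prefixed keys map to VCF INFO
#' fields); values are case-sensitive. For example:
#'
#' `GT_TYPE = 2 & (INFO_EFF_IMPACT = HIGH | INFO_EFF_IMPACT = MODERATE)`
#'
#' @param text query string.
#' @param keys optional character vector of valid keys; unknown keys then
#'   raise an error naming the valid ones.
#' @return a `variant_query` AST object.
#' @export
parse_query <- function(text, keys = NULL) {
  toks <- query_tokens(text)
  st <- new.env()
  st$toks <- toks
  st$i <- 1L
  ast <- parse_or(st, text)
  if (st$i <= nrow(st$toks)) {
    abort(sprintf("syntax error at column %d: unexpected '%s'",
                  st$toks$col[st$i], st$toks$value[st$i]),
          class = "strainforge_query_error")
  }
  if (!is.null(keys)) {
    used <- query_keys(ast)
    bad <- setdiff(toupper(used), toupper(keys))
    if (length(bad)) {
      abort(sprintf("unknown key(s): %s. Valid keys: %s",
                    paste(bad, collapse = ", "),
                    paste(sort(keys), collapse = ", ")),
            class = "strainforge_query_error")
    }
  }
  structure(ast, class = "variant_query")
}

query_tokens <- function(text) {
  pat <- "(>=|<=|!=|=|<|>|&|\\||\\(|\\)|\"[^\"]*\"|[A-Za-z_][A-Za-z0-9_.]*|-?[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    abort("syntax error at column 1: empty query",
          class = "strainforge_query_error")
  }
  vals <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  cols <- as.integer(m)
  ## anything outside tokens and whitespace is an error
  covered <- logical(nchar(text))
  for (j in seq_along(vals)) {
    covered[cols[j]:(cols[j] + nchar(vals[j]) - 1L)] <- TRUE
  }
  stray <- which(!covered & strsplit(text, "")[[1]] != " ")
  if (length(stray)) {
    abort(sprintf("syntax error at column %d: unexpected character '%s'",
                  stray[1], substr(text, stray[1], stray[1])),
          class = "strainforge_query_error")
  }
  type <- dplyr::case_when(
    vals %in% c("=", "!=", "<", "<=", ">", ">=") ~ "op",
    vals == "&" ~ "and", vals == "|" ~ "or",
    vals == "(" ~ "lparen", vals == ")" ~ "rparen",
    grepl("^\"", vals) ~ "string",
    grepl("^-?[0-9]", vals) ~ "number",
    TRUE ~ "word")
  tibble(value = vals, type = type, col = cols)
}

peek <- function(st) if (st$i <= nrow(st$toks)) st$toks[st$i, ] else NULL
advance <- function(st) { t <- st$toks[st$i, ]; st$i <- st$i + 1L; t }

parse_or <- function(st, text) {
  left <- parse_and(st, text)
  while (!is.null(p <- peek(st)) && p$type == "or") {
    advance(st)
    right <- parse_and(st, text)
    left <- list(node = "or", left = left, right = right)
  }
  left
}

parse_and <- function(st, text) {
  left <- parse_factor(st, text)
  while (!is.null(p <- peek(st)) && p$type == "and") {
    advance(st)
    right <- parse_factor(st, text)
    left <- list(node = "and", left = left, right = right)
  }
  left
}

parse_factor <- function(st, text) {
  p <- peek(st)
  if (is.null(p)) {
    abort(sprintf("syntax error at column %d: unexpected end of query",
                  nchar(text) + 1L),
          class = "strainforge_query_error")
  }
  if (p$type == "lparen") {
    advance(st)
    inner <- parse_or(st, text)
    q <- peek(st)
    if (is.null(q) || q$type != "rparen") {
      abort(sprintf("syntax error at column %d: expected ')'",
                    if (is.null(q)) nchar(text) + 1L else q$col),
            class = "strainforge_query_error")
    }
    advance(st)
    return(inner)
  }
  if (p$type != "word") {
    abort(sprintf("syntax error at column %d: expected a key, got '%s'",
                  p$col, p$value),
          class = "strainforge_query_error")
  }
  key <- advance(st)
  op <- peek(st)
  if (is.null(op) || op$type != "op") {
    abort(sprintf("syntax error at column %d: expected an operator after '%s'",
                  if (is.null(op)) nchar(text) + 1L else op$col, key$value),
          class = "strainforge_query_error")
  }
  advance(st)
  val <- peek(st)
  if (is.null(val) || !val$type %in% c("word", "number", "string")) {
    abort(sprintf("syntax error at column %d: expected a value",
                  if (is.null(val)) nchar(text) + 1L else val$col),
          class = "strainforge_query_error")
  }
  advance(st)
  value <- val$value
  if (val$type == "string") value <- gsub('^"|"$', "", value)
  list(node = "cmp", key = key$value, op = op$value,
       value = value, numeric = val$type == "number")
}

query_keys <- function(ast) {
  if (ast$node == "cmp") return(ast$key)
  c(query_keys(ast$left), query_keys(ast$right))
}

#' @export
print.variant_query <- function(x, ...) {
  cat(deparse_query(x), "\n")
  invisible(x)
}

deparse_query <- function(ast) {
  if (ast$node == "cmp") {
    return(sprintf("%s %s %s", ast$key, ast$op, ast$value))
  }
  sprintf("(%s %s %s)", deparse_query(ast$left),
          if (ast$node == "and") "&" else "|", deparse_query(ast$right))
}

#' Evaluate a query against the evidence table
#'
#' In the `melted` view, returns the matching rows. In the `cast` view,
#' returns one row per variant that has at least one matching melted row
#' (ANY-sample semantics), with the matching samples aggregated into a
#' comma-separated `SAMPLES` column and `N_SAMPLES` count.
#'
#' @param table evidence tibble from [build_evidence_table()].
#' @param query a `variant_query` or query text.
#' @param view `"melted"` or `"cast"`.
#' @return tibble of matching rows.
#' @export
evaluate_query <- function(table, query, view = c("melted", "cast")) {
  view <- match.arg(view)
  if (is.character(query)) query <- parse_query(query, keys = names(table))
  mask <- eval_node(query, table)
  hits <- table[which(mask), , drop = FALSE]
  if (view == "melted") return(hits)
  hits |>
    group_by(.data$UID) |>
    summarise(CHROM = .data$CHROM[1], POSITION = .data$POSITION[1],
              REF = .data$REF[1], ALT = .data$ALT[1],
              SAMPLES = paste(sort(.data$SAMPLE_ID), collapse = ","),
              N_SAMPLES = dplyr::n_distinct(.data$SAMPLE_ID),
              .groups = "drop") |>
    arrange(.data$CHROM, .data$POSITION)
}

eval_node <- function(ast, table) {
  if (ast$node == "and") {
    return(eval_node(ast$left, table) & eval_node(ast$right, table))
  }
  if (ast$node == "or") {
    return(eval_node(ast$left, table) | eval_node(ast$right, table))
  }
  cname <- names(table)[match(toupper(ast$key), toupper(names(table)))]
  if (is.na(cname)) {
    abort(sprintf("unknown key '%s'. Valid keys: %s", ast$key,
                  paste(sort(names(table)), collapse = ", ")),
          class = "strainforge_query_error")
  }
  col <- table[[cname]]
  if (is.numeric(col)) {
    num <- suppressWarnings(as.numeric(ast$value))
    if (is.na(num)) {
      abort(sprintf("key %s is numeric but value '%s' is not", cname,
                    ast$value),
            class = "strainforge_query_error")
    }
    res <- switch(ast$op, "=" = col == num, "!=" = col != num,
                  "<" = col < num, "<=" = col <= num, ">" = col > num,
                  ">=" = col >= num)
  } else {
    if (!ast$op %in% c("=", "!=")) {
      abort(sprintf("ordering operator '%s' applied to non-numeric key %s",
                    ast$op, cname),
            class = "strainforge_query_error")
    }
    res <- switch(ast$op, "=" = col == ast$value, "!=" = col != ast$value)
  }
  res & !is.na(res)
}
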