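# Atom selection mini-language.
#
# Grammar (case-insensitive keywords, atom values case-sensitive except
# element):
#   expr    := and_expr ('or' and_expr)*
#   and_expr:= unary ('and' unary)*
#   unary   := 'not' unary | '(' expr ')' | primary
#   primary := 'chain' value+ | 'resname' value+ | 'name' value+
#            | 'element' value+ | 'resid' range (',' range)* | 'all' | 'het'
#   range   := INT | INT '-' INT          (inclusive on both ends)
# Parsing is total: an invalid expression raises an error, it never silently
# matches nothing.

.sel_tokenize <- function(expr) {
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  expr <- gsub(",", " , ", expr)
  toks <- strsplit(trimws(expr), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

.KEYWORDS <- c("and", "or", "not", "all", "het", "chain", "resid",
               "resname", "name", "element", "(", ")", ",")

#' Select atom indices with a selection expression
#'
#' @param traj a `Trajectory` or `Structure`
#' @param expr selection string, e.g. `"chain R and resid 54-80 and name CA"`
#' @return integer vector of atom indices in topology order (possibly empty)
#' @examples
#' h <- make_ideal_helix(n_res = 8)
#' select_atoms(h, "name CA")
#' @export
select_atoms <- function(traj, expr) {
  atoms <- if (inherits(traj, c("Trajectory", "Structure"))) traj$atoms else traj
  toks <- .sel_tokenize(expr)
  if (length(toks) == 0) stopf("selection error: empty expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- peek(); pos <<- pos + 1L; t }

  parse_primary <- function() {
    t <- advance()
    if (is.na(t)) stopf("selection error: unexpected end of expression")
    kw <- tolower(t)
    if (kw == "(") {
      m <- parse_or()
      if (!identical(tolower(peek()), ")"))
        stopf("selection error: missing ')'")
      advance()
      return(m)
    }
    if (kw == "all") return(rep(TRUE, nrow(atoms)))
    if (kw == "het") return(atoms$het)
    if (kw %in% c("chain", "resname", "name", "element")) {
      vals <- character(0)
      while (!is.na(peek()) && !(tolower(peek()) %in% .KEYWORDS)) {
        vals <- c(vals, advance())
      }
      if (length(vals) == 0)
        stopf("selection error: '%s' needs at least one value", kw)
      col <- switch(kw, chain = atoms$chain, resname = atoms$resname,
                    name = atoms$name, element = atoms$element)
      if (kw == "element") vals <- toupper(vals)
      return(col %in% vals)
    }
    if (kw == "resid") {
      ok <- rep(FALSE, nrow(atoms))
      got <- FALSE
      repeat {
        v <- peek()
        if (is.na(v) || tolower(v) %in% setdiff(.KEYWORDS, ","))
          break
        advance()
        if (v == ",") next
        if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
          m <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
          lo <- as.integer(m[2]); hi <- as.integer(m[3])
          if (lo > hi) stopf("selection error: bad resid range '%s'", v)
          ok <- ok | (atoms$resid >= lo & atoms$resid <= hi)
        } else if (grepl("^-?[0-9]+$", v)) {
          ok <- ok | atoms$resid == as.integer(v)
        } else stopf("selection error: bad resid value '%s'", v)
        got <- TRUE
      }
      if (!got) stopf("selection error: 'resid' needs at least one value")
      return(ok)
    }
    stopf("selection error: unexpected token '%s'", t)
  }

  parse_unary <- function() {
    if (identical(tolower(peek()), "not")) {
      advance()
      return(!parse_unary())
    }
    parse_primary()
  }
  parse_and <- function() {
    m <- parse_unary()
    while (identical(tolower(peek()), "and")) {
      advance()
      m <- m & parse_unary()
    }
    m
  }
  parse_or <- function() {
    m <- parse_and()
    while (identical(tolower(peek()), "or")) {
      advance()
      m <- m | parse_and()
    }
    m
  }

  mask <- parse_or()
  if (pos <= length(toks))
    stopf("selection error: trailing tokens from '%s'", toks[pos])
  which(mask)
}
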