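# Gene-protein-reaction rule parsing.
#
# A GPR is a Boolean expression over gene identifiers with "and" (complex
# subunits) and "or" (isozymes).  "and" binds tighter than "or" when
# parentheses are absent.  A rule's complexes are its minimal satisfying gene
# sets: the disjunctive normal form with duplicate and superset disjuncts
# removed.

.gpr_tokenize <- function(rule) {
  tokens <- list(); pos <- integer(0)
  i <- 1L; nch <- nchar(rule)
  while (i <= nch) {
    ch <- substr(rule, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1L]] <- ch; pos <- c(pos, i); i <- i + 1L; next
    }
    if (ch %in% c("&", "|")) {
      two <- substr(rule, i, i + 1L)
      op <- if (ch == "&") "and" else "or"
      tokens[[length(tokens) + 1L]] <- op; pos <- c(pos, i)
      i <- i + (if (two %in% c("&&", "||")) 2L else 1L); next
    }
    j <- i
    while (j <= nch && !grepl("^[\\s()&|]$", substr(rule, j, j), perl = TRUE))
      j <- j + 1L
    word <- substr(rule, i, j - 1L)
    lw <- tolower(word)
    tokens[[length(tokens) + 1L]] <- if (lw %in% c("and", "or")) lw else word
    pos <- c(pos, i)
    i <- j
  }
  list(tokens = unlist(tokens), pos = pos)
}

# recursive-descent parser producing DNF as a list of gene-id vectors
.gpr_parse_expr <- function(st) {
  disj <- .gpr_parse_term(st)
  while (!is.null(.gpr_peek(st)) && identical(.gpr_peek(st), "or")) {
    .gpr_next(st)
    disj <- c(disj, .gpr_parse_term(st))
  }
  disj
}

.gpr_parse_term <- function(st) {
  conj <- .gpr_parse_factor(st)
  while (!is.null(.gpr_peek(st)) && identical(.gpr_peek(st), "and")) {
    .gpr_next(st)
    rhs <- .gpr_parse_factor(st)
    conj <- unlist(lapply(conj, function(a)
      lapply(rhs, function(b) unique(c(a, b)))), recursive = FALSE)
  }
  conj
}

.gpr_parse_factor <- function(st) {
  tok <- .gpr_peek(st)
  if (is.null(tok))
    stop("GPR parse error at position ", .gpr_pos(st), ": unexpected end of rule")
  if (identical(tok, "(")) {
    .gpr_next(st)
    inner <- .gpr_parse_expr(st)
    if (!identical(.gpr_peek(st), ")"))
      stop("GPR parse error at position ", .gpr_pos(st), ": expected ')'")
    .gpr_next(st)
    return(inner)
  }
  if (tok %in% c(")", "and", "or"))
    stop("GPR parse error at position ", .gpr_pos(st),
         ": unexpected '", tok, "'")
  .gpr_next(st)
  list(tok)
}

.gpr_peek <- function(st) {
  if (st$i > length(st$tokens)) NULL else st$tokens[[st$i]]
}
.gpr_next <- function(st) { st$i <- st$i + 1L; invisible(st) }
.gpr_pos <- function(st) {
  if (st$i > length(st$pos)) st$end else st$pos[st$i]
}

#' Parse a gene-reaction rule into complexes
#'
#' Expands a Boolean gene-protein-reaction rule into its minimal satisfying
#' gene sets.  Each set is one candidate enzyme complex: \code{"and"} joins
#' subunits of one complex, \code{"or"} separates alternative (isozyme)
#' complexes, and \code{"and"} binds tighter than \code{"or"}.  Duplicate and
#' superset gene sets are removed, so the result is the canonical minimal
#' disjunctive normal form.
#'
#' @param rule a GPR string, e.g. \code{"(g1 and g2) or g3"}.  \code{"&"} and
#'   \code{"|"} are accepted as synonyms.  An empty rule denotes a spontaneous
#'   reaction.
#' @return a list of character vectors, each the sorted gene ids of one
#'   complex; an empty list for an empty rule.
#' @examples
#' parseGeneRule("(g1 or g2) and g3")
#' @export
parseGeneRule <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(list())
  tk <- .gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$tokens <- tk$tokens; st$pos <- tk$pos; st$i <- 1L
  st$end <- nchar(rule) + 1L
  disj <- .gpr_parse_expr(st)
  if (!is.null(.gpr_peek(st)))
    stop("GPR parse error at position ", .gpr_pos(st),
         ": unexpected '", .gpr_peek(st), "'")
  disj <- unique(lapply(disj, function(g) sort(unique(g))))
  # keep only minimal sets (drop supersets of another disjunct)
  keep <- vapply(seq_along(disj), function(i) {
    !any(vapply(seq_along(disj), function(j)
      j != i && length(disj[[j]]) < length(disj[[i]]) &&
        all(disj[[j]] %in% disj[[i]]), logical(1)))
  }, logical(1))
  disj <- disj[keep]
  disj[order(vapply(disj, paste, "", collapse = "\r"))]
}

# all gene ids mentioned by a rule (tolerant; used by validity checks)
.gpr_genes <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(character(0))
  tk <- .gpr_tokenize(rule)$tokens
  setdiff(tk, c("and", "or", "(", ")"))
}
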