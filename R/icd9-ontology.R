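# ICD-9-CM ontology reconstruction: canonical forms, levels, ancestor
# chains and least-common-ancestor queries over the five-level hierarchy
# (root / chapter / section / category / subcategory / extension).

.EN <- "–"  # en-dash used in displayed range tokens; hyphen accepted
.ROOT <- "ROOT"

# package-local cache for the packaged chapter/section range tables
.unidiag_cache <- new.env(parent = emptyenv())

.icd9Tables <- function() {
  if (!is.null(.unidiag_cache$tables)) return(.unidiag_cache$tables)
  chp <- utils::read.delim(system.file("extdata", "icd9_chapters.tsv",
                                       package = "unidiag"),
                           colClasses = "character")
  sec <- utils::read.delim(system.file("extdata", "icd9_sections.tsv",
                                       package = "unidiag"),
                           colClasses = "character")
  for (tb in c("chp", "sec")) {
    t <- get(tb)
    t$token <- paste0(t$start, .EN, t$end)
    t$kstart <- .stemKey(t$start)
    t$kend <- .stemKey(t$end)
    assign(tb, t)
  }
  sec$chapter <- chp$token[.rangeIndex(sec$kstart, chp)]
  .unidiag_cache$tables <- list(chapters = chp, sections = sec)
  .unidiag_cache$tables
}

# numeric sort key for a category stem; V and E stems are offset so that
# range comparisons never cross letter classes
.stemKey <- function(stem) {
  cls <- substr(stem, 1L, 1L)
  num <- suppressWarnings(as.numeric(sub("^[VE]", "", stem)))
  num + ifelse(cls == "V", 10000, ifelse(cls == "E", 20000, 0))
}

.rangeIndex <- function(key, table) {
  vapply(key, function(k) {
    i <- which(table$kstart <= k & table$kend >= k)
    if (length(i)) i[1L] else NA_integer_
  }, integer(1))
}

.padStem <- function(cls, digits) {
  width <- if (identical(cls, "V")) 2L else 3L
  pad <- pmax(width - nchar(digits), 0L)
  paste0(cls, strrep("0", pad), digits)
}

.canonOne <- function(raw) {
  up <- toupper(trimws(raw))
  fail <- function(why) stop("malformed ICD-9 code '", raw, "': ", why,
                             call. = FALSE)
  if (!nzchar(up)) fail("empty string")
  if (up %in% c("ROOT", "ROOT NODE")) {
    return(list(canonical = .ROOT, level = 0L, kind = "root"))
  }
  dash <- gsub(.EN, "-", up, fixed = TRUE)
  if (grepl("-", dash, fixed = TRUE)) {
    ends <- strsplit(dash, "-", fixed = TRUE)[[1L]]
    if (length(ends) != 2L) fail("range token needs exactly two endpoints")
    ends <- vapply(ends, function(e) {
      m <- regmatches(e, regexec("^([VE]?)([0-9]+)$", e))[[1L]]
      if (!length(m)) fail("invalid range endpoint")
      .padStem(m[2L], m[3L])
    }, character(1))
    token <- paste0(ends[1L], .EN, ends[2L])
    tabs <- .icd9Tables()
    if (token %in% tabs$chapters$token)
      return(list(canonical = token, level = 1L, kind = "chapter"))
    if (token %in% tabs$sections$token)
      return(list(canonical = token, level = 2L, kind = "section"))
    fail("range matches no packaged chapter or section")
  }
  m <- regmatches(up, regexec("^([VE]?)([0-9]+)(\\.([0-9]+))?$", up))[[1L]]
  if (!length(m)) fail("only digits, an optional leading V/E and one dot allowed")
  cls <- m[2L]
  stem_w <- if (cls == "E") 3L else if (cls == "V") 2L else 3L
  dec_max <- if (cls == "E") 1L else 2L
  if (m[4L] == "") {  # dotless (MIMIC dialect): split after the stem digits
    dg <- m[3L]
    if (nchar(dg) <= stem_w) { stem <- dg; dec <- "" }
    else { stem <- substr(dg, 1L, stem_w); dec <- substr(dg, stem_w + 1L, nchar(dg)) }
  } else {
    stem <- m[3L]; dec <- m[5L]
  }
  if (nchar(stem) > stem_w) fail("category stem too long")
  if (nchar(dec) > dec_max) fail("too many digits after the category stem")
  stem <- .padStem(cls, stem)
  level <- 3L + nchar(dec)
  list(canonical = if (nchar(dec)) paste0(stem, ".", dec) else stem,
       level = level,
       kind = c("category", "subcategory", "extension")[level - 2L])
}

#' Canonicalize ICD-9 code strings
#'
#' Accepts both dotted (`"038.9"`) and dotless MIMIC-dialect (`"0389"`)
#' code strings, range tokens for chapters/sections (`"520-579"`, en-dash
#' or hyphen), and the root sentinel `"ROOT"`.  The canonical form is
#' dotted with leading zeros preserved; dotless forms gain a dot after the
#' third significant character (after the fourth for E-codes).
#'
#' @param raw character vector of code strings.
#' @return data.frame with columns `raw`, `canonical`, `level` (0-5) and
#'   `kind` (root/chapter/section/category/subcategory/extension).
#' @examples
#' icd9Canonicalize(c("0389", "38.9", "V5861", "E9500", "520-579"))
#' @export
icd9Canonicalize <- function(raw) {
  stopifnot(is.character(raw) | is.factor(raw), length(raw) > 0L)
  raw <- as.character(raw)
  parts <- lapply(raw, .canonOne)
  data.frame(raw = raw,
             canonical = vapply(parts, `[[`, character(1), "canonical"),
             level = vapply(parts, `[[`, integer(1), "level"),
             kind = vapply(parts, `[[`, character(1), "kind"),
             stringsAsFactors = FALSE)
}

# full ancestor chain root -> ... -> code for a canonical code string
.ancestorChain <- function(canonical) {
  info <- .canonOne(canonical)
  can <- info$canonical
  if (info$level == 0L) return(.ROOT)
  tabs <- .icd9Tables()
  if (info$kind == "chapter") return(c(.ROOT, can))
  if (info$kind == "section") {
    i <- match(can, tabs$sections$token)
    return(c(.ROOT, tabs$sections$chapter[i], can))
  }
  stem <- sub("\\..*$", "", can)
  key <- .stemKey(stem)
  ci <- .rangeIndex(key, tabs$chapters)
  if (is.na(ci))
    stop("ICD-9 code '", canonical, "': category stem '", stem,
         "' matches no chapter range", call. = FALSE)
  si <- .rangeIndex(key, tabs$sections)
  chain <- c(.ROOT, tabs$chapters$token[ci], tabs$sections$token[si], stem)
  dec <- sub("^[^.]*\\.?", "", can)
  if (nchar(dec) >= 1L) chain <- c(chain, paste0(stem, ".", substr(dec, 1L, 1L)))
  if (nchar(dec) == 2L) chain <- c(chain, can)
  chain
}

#' Build the ICD-9 ontology over a code universe
#'
#' Materialises every input code plus its full ancestor closure (category,
#' section, chapter, root).  Virtual sibling padding is never created:
#' least-common-ancestor queries only need the actual ancestor chains.
#'
#' @param codes character vector of raw code strings (dotted or dotless);
#'   may be empty, giving a root-only tree.
#' @return an [ICD9Ontology-class] object.
#' @examples
#' ont <- buildOntology(c("550.12", "550.13", "541"))
#' ontologyNodes(ont)
#' @export
buildOntology <- function(codes = character()) {
  tabs <- .icd9Tables()
  chains <- lapply(unique(as.character(codes)), function(cd) {
    info <- .canonOne(cd)
    if (info$level == 0L) return(.ROOT)
    .ancestorChain(info$canonical)
  })
  nodes <- .ROOT
  parent <- stats::setNames(NA_character_, .ROOT)
  for (ch in chains) {
    if (length(ch) > 1L)
      parent[ch[-1L]] <- ch[-length(ch)]
    nodes <- union(nodes, ch)
  }
  info <- do.call(rbind, lapply(nodes, function(n) {
    i <- .canonOne(n)
    data.frame(canonical = i$canonical, level = i$level, kind = i$kind,
               stringsAsFactors = FALSE)
  }))
  info$parent <- unname(parent[info$canonical])
  new("ICD9Ontology", nodes = info,
      chapters = tabs$chapters[, c("start", "end", "label", "token")],
      sections = tabs$sections[, c("start", "end", "label", "token", "chapter")])
}

.requireNode <- function(ontology, code) {
  can <- vapply(code, function(cd) .canonOne(cd)$canonical, character(1))
  miss <- setdiff(can, ontology@nodes$canonical)
  if (length(miss))
    stop("code(s) not in ontology: ", paste(miss, collapse = ", "),
         call. = FALSE)
  unname(can)
}

#' Level depth of codes in the ontology
#'
#' Root has level 0; chapters, sections, categories, subcategories and
#' extensions have levels 1-5.
#'
#' @param ontology an [ICD9Ontology-class].
#' @param code character vector of codes (canonicalized on the fly); each
#'   must belong to the ontology.
#' @return integer vector of level depths.
#' @export
codeLevel <- function(ontology, code) {
  stopifnot(is(ontology, "ICD9Ontology"))
  can <- .requireNode(ontology, code)
  ontology@nodes$level[match(can, ontology@nodes$canonical)]
}

#' Information content of codes
#'
#' The information content of a code is its level depth in the ontology:
#' 0 at the root, increasing to 5 at extension codes.  Deeper codes are
#' more specific concepts.
#'
#' @inheritParams codeLevel
#' @return integer vector of IC values in 0..5.
#' @examples
#' ont <- buildOntology(c("550.12", "541"))
#' informationContent(ont, c("550.12", "541", "ROOT"))
#' @export
informationContent <- function(ontology, code) codeLevel(ontology, code)

#' Least common ancestor of code pairs
#'
#' The deepest ontology node lying on both codes' root paths.  Codes in
#' different chapters share only the root.
#'
#' @param ontology an [ICD9Ontology-class].
#' @param a,b character vectors of codes (recycled to a common length).
#' @return character vector of canonical LCA tokens (possibly `"ROOT"`).
#' @examples
#' ont <- buildOntology(c("550.12", "550.13", "541"))
#' icd9LCA(ont, "550.12", "550.13")  # "550.1"
#' icd9LCA(ont, "541", "550.13")     # the shared digestive chapter
#' @export
icd9LCA <- function(ontology, a, b) {
  stopifnot(is(ontology, "ICD9Ontology"))
  n <- max(length(a), length(b))
  a <- rep_len(.requireNode(ontology, a), n)
  b <- rep_len(.requireNode(ontology, b), n)
  vapply(seq_len(n), function(i) {
    ca <- .ancestorChain(a[i]); cb <- .ancestorChain(b[i])
    common <- intersect(ca, cb)
    common[length(common)]  # chains are root-first, so last common is deepest
  }, character(1))
}

#' Full ancestor chain of a code
#'
#' @inheritParams codeLevel
#' @param code a single code string.
#' @return character vector from `"ROOT"` down to the code itself.
#' @export
icd9Ancestors <- function(ontology, code) {
  stopifnot(is(ontology, "ICD9Ontology"), length(code) == 1L)
  .ancestorChain(.requireNode(ontology, code))
}

#' Packaged short titles for common diagnosis codes
#'
#' A small convenience dictionary (canonical code, short title) used to
#' label report entries; mirrors the usual code-description lookup
#' tables.  Synthetic-cohort and report writers accept any data.frame of
#' the same shape.
#'
#' @return data.frame with columns `code`, `short_title`.
#' @export
icd9Titles <- function() {
  utils::read.csv(system.file("extdata", "icd9_titles.csv",
                              package = "unidiag"),
                  colClasses = "character")
}

#' @describeIn buildOntology node table accessor (canonical, level, kind,
#'   parent).
#' @param ontology an [ICD9Ontology-class].
#' @export
ontologyNodes <- function(ontology) {
  stopifnot(is(ontology, "ICD9Ontology"))
  ontology@nodes
}

setMethod("show", "ICD9Ontology", function(object) {
  lv <- table(factor(object@nodes$level, levels = 0:5))
  cat("ICD9Ontology with", nrow(object@nodes), "materialised nodes\n")
  cat("  nodes per level 0..5:", paste(lv, collapse = "/"), "\n")
  cat("  packaged ranges:", nrow(object@chapters), "chapters,",
      nrow(object@sections), "sections\n")
})
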