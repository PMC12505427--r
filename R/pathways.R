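# Nutritional pathway completeness and consortium complementarity.
#
# A pathway catalog lists, per pathway, its ordered enzymatic steps; each
# step is a set of alternative gene symbols (isozymes or alternative
# routes).  Presence is called by annotated gene symbol (after synonym
# normalisation), not by homology search, so it is exactly testable; an
# externally produced symbol table can be supplied for real genomes.

PATHWAY_CLASSES <- c("EAA", "non-essential AA", "B-vitamin", "cofactor")

# Genes treated as host-complemented / consistently absent across the
# sequenced consortia; steps consisting solely of these do not block a
# "jointly complete" call.
DEFAULT_WHITELIST <- c("ilvA", "hisN", "yigB")

#' Load a pathway catalog
#'
#' TSV catalogs have header columns pathway_id, display_name, class,
#' step_index, alternatives (comma-separated gene symbols); YAML catalogs
#' mirror the same structure (\code{pathways:} list with \code{steps} as a
#' list of vectors, optional \code{synonyms:} map).
#'
#' @param path catalog file (.tsv or .yml/.yaml); defaults to the shipped
#'   catalog of the 10 essential amino acid pathways plus cysteine,
#'   riboflavin and biotin
#' @return object of class \code{pathway_catalog}
#' @export
load_catalog <- function(path = system.file("extdata",
                                            "pathway_catalog.tsv",
                                            package = "endosym")) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    pws <- lapply(y$pathways, function(p) {
      list(pathway_id = p$pathway_id,
           display_name = p$display_name %||% p$pathway_id,
           class = p$class,
           steps = lapply(p$steps, as.character))
    })
    syn <- unlist(y$synonyms %||% list())
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
    req <- c("pathway_id", "class", "step_index", "alternatives")
    if (!all(req %in% names(df))) {
      stop("catalog TSV must have columns: ", paste(req, collapse = ", "))
    }
    pws <- lapply(split(df, factor(df$pathway_id,
                                   levels = unique(df$pathway_id))),
                  function(d) {
      d <- d[order(d$step_index), , drop = FALSE]
      list(pathway_id = d$pathway_id[1],
           display_name = (d$display_name %||% d$pathway_id)[1],
           class = d$class[1],
           steps = lapply(strsplit(d$alternatives, ","), trimws))
    })
    names(pws) <- NULL
    syn <- character(0)
  }
  new_catalog(pws, synonym_map = syn)
}

#' Construct and validate a pathway catalog
#'
#' @param pathways list of pathway entries (pathway_id, display_name,
#'   class, steps = list of character vectors of alternative symbols)
#' @param synonym_map named character vector mapping synonyms to canonical
#'   symbols
#' @return object of class \code{pathway_catalog}
#' @export
new_catalog <- function(pathways, synonym_map = character(0)) {
  ids <- vapply(pathways, `[[`, "", "pathway_id")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway_id: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  for (p in pathways) {
    if (!p$class %in% PATHWAY_CLASSES) {
      stop(sprintf("pathway %s: unknown class '%s'", p$pathway_id, p$class))
    }
    if (!length(p$steps) || any(!vapply(p$steps, length, 0L))) {
      stop(sprintf("pathway %s: empty step", p$pathway_id))
    }
  }
  syn <- unlist(synonym_map)
  if (length(syn)) {
    # resolve chains and reject cycles
    for (s in names(syn)) {
      seen <- s
      cur <- s
      while (cur %in% names(syn)) {
        cur <- syn[[cur]]
        if (cur %in% seen) stop("synonym cycle involving '", s, "'")
        seen <- c(seen, cur)
      }
      syn[[s]] <- cur
    }
  }
  structure(list(pathways = stats::setNames(pathways, ids),
                 synonym_map = syn),
            class = "pathway_catalog")
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat(sprintf("<pathway_catalog> %d pathways, %d steps, %d synonyms\n",
              length(x$pathways),
              sum(vapply(x$pathways, function(p) length(p$steps), 0L)),
              length(x$synonym_map)))
  invisible(x)
}

#' Save a catalog as TSV
#' @param catalog a \code{pathway_catalog}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
save_catalog <- function(catalog, path) {
  rows <- do.call(rbind, lapply(catalog$pathways, function(p) {
    data.frame(pathway_id = p$pathway_id, display_name = p$display_name,
               class = p$class, step_index = seq_along(p$steps),
               alternatives = vapply(p$steps, paste, "", collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

catalog_symbols <- function(catalog) {
  unique(unlist(lapply(catalog$pathways, function(p) unlist(p$steps))))
}

.canonical <- function(symbols, catalog) {
  syn <- catalog$synonym_map
  vocab <- catalog_symbols(catalog)
  out <- as.character(symbols)
  if (length(syn)) {
    hit <- tolower(out) %in% tolower(names(syn))
    out[hit] <- syn[match(tolower(out[hit]), tolower(names(syn)))]
  }
  # case-insensitive match onto catalog vocabulary
  m <- match(tolower(out), tolower(vocab))
  ifelse(is.na(m), out, vocab[m])
}

#' Profile gene presence against a catalog
#'
#' A catalog symbol is \code{present} in a genome when some non-pseudo CDS
#' carries it (after synonym normalisation, case-insensitively),
#' \code{present_split} when it is carried by a merged split gene, and
#' \code{absent} otherwise.
#'
#' @param features a \code{feature_set} (may span several genomes)
#' @param merged optional merged-gene annotation
#'   (\code{\link{write_merged_annotation}} table) whose \code{gene}
#'   symbols are scored as \code{present_split}
#' @param catalog a \code{pathway_catalog}
#' @return matrix of class \code{presence_matrix} (genomes x symbols) with
#'   values "absent"/"present"/"present_split"
#' @export
profile_presence <- function(features, merged = NULL,
                             catalog = load_catalog()) {
  df <- as.data.frame(features)
  genomes <- unique(df$genome_id)
  vocab <- catalog_symbols(catalog)
  m <- matrix("absent", nrow = length(genomes), ncol = length(vocab),
              dimnames = list(genomes, vocab))
  split_tags <- unique(c(merged$first_locus_tag, merged$second_locus_tag))
  cds <- df[df$type == "CDS" & !df$pseudo & !is.na(df$gene) &
            !(df$locus_tag %in% split_tags), , drop = FALSE]
  for (i in seq_len(nrow(cds))) {
    sym <- .canonical(cds$gene[i], catalog)
    if (sym %in% vocab) m[cds$genome_id[i], sym] <- "present"
  }
  if (!is.null(merged) && nrow(merged)) {
    for (i in seq_len(nrow(merged))) {
      if (is.na(merged$gene[i])) next
      sym <- .canonical(merged$gene[i], catalog)
      if (sym %in% vocab && merged$genome_id[i] %in% genomes &&
          m[merged$genome_id[i], sym] != "present") {
        m[merged$genome_id[i], sym] <- "present_split"
      }
    }
  }
  structure(m, class = c("presence_matrix", class(m)))
}

#' Read a presence matrix from a TSV fixture
#'
#' Expected columns: genome, gene, status (present/present_split); any
#' further columns (host, symbiont, source) are carried along as the
#' \code{"meta"} attribute.
#'
#' @param path TSV file
#' @param catalog catalog defining the symbol vocabulary
#' @return a \code{presence_matrix}
#' @export
read_presence <- function(path, catalog = load_catalog()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  stopifnot(all(c("genome", "gene", "status") %in% names(df)))
  genomes <- unique(df$genome)
  vocab <- catalog_symbols(catalog)
  m <- matrix("absent", nrow = length(genomes), ncol = length(vocab),
              dimnames = list(genomes, vocab))
  for (i in seq_len(nrow(df))) {
    sym <- .canonical(df$gene[i], catalog)
    if (!sym %in% vocab) {
      stop("fixture symbol not in catalog vocabulary: ", df$gene[i])
    }
    m[df$genome[i], sym] <- df$status[i]
  }
  structure(m, class = c("presence_matrix", class(m)), meta = df)
}

#' Pathway completeness per genome
#'
#' A step is covered when at least one of its alternative symbols is
#' present or present_split; completeness is covered/total steps.
#'
#' @param presence a \code{presence_matrix}
#' @param catalog the matching \code{pathway_catalog}
#' @return data.frame of class \code{completeness_report} with one row per
#'   genome x pathway; the \code{missing} list-column holds the
#'   alternative-symbol sets of uncovered steps
#' @export
completeness <- function(presence, catalog = load_catalog()) {
  genomes <- rownames(presence)
  rows <- list()
  cover <- list()  # pathway -> genomes x steps logical matrix
  for (p in catalog$pathways) {
    cov <- matrix(FALSE, nrow = length(genomes), ncol = length(p$steps),
                  dimnames = list(genomes, NULL))
    for (s in seq_along(p$steps)) {
      alts <- intersect(p$steps[[s]], colnames(presence))
      if (length(alts)) {
        cov[, s] <- apply(presence[, alts, drop = FALSE] != "absent", 1, any)
      }
    }
    cover[[p$pathway_id]] <- cov
    for (g in genomes) {
      covered <- sum(cov[g, ])
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g, pathway_id = p$pathway_id, class = p$class,
        covered_steps = covered, total_steps = length(p$steps),
        completeness = covered / length(p$steps),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$missing <- I(list(p$steps[!cov[g, ]]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("completeness_report", "data.frame"),
            step_coverage = cover,
            catalog_digest = .catalog_digest(catalog))
}

.catalog_digest <- function(catalog) {
  paste(vapply(catalog$pathways, function(p) {
    paste(p$pathway_id, p$class,
          paste(vapply(p$steps, paste, "", collapse = "/"), collapse = ";"))
  }, ""), collapse = "|")
}

#' Consortium-level pathway union
#'
#' A step is covered by the consortium when any member genome covers it.
#' \code{jointly_complete} is TRUE when every step not fully whitelisted
#' is covered; a step is whitelisted when all of its alternative symbols
#' are on the whitelist of host-complemented/consistently absent genes.
#'
#' @param reports list of \code{completeness_report} objects (or a single
#'   report covering several genomes) computed from the same catalog
#' @param whitelist gene symbols whose absence does not block joint
#'   completeness (default ilvA, hisN, yigB)
#' @param catalog the shared catalog
#' @return data.frame of class \code{consortium_report} with per-pathway
#'   union completeness, provider sets and sole-provider steps
#' @export
consortium_union <- function(reports,
                             whitelist = DEFAULT_WHITELIST,
                             catalog = load_catalog()) {
  if (inherits(reports, "completeness_report")) reports <- list(reports)
  digests <- vapply(reports, attr, "", "catalog_digest")
  if (length(unique(digests)) != 1 ||
      digests[1] != .catalog_digest(catalog)) {
    stop("completeness reports were not computed from the same catalog")
  }
  rows <- list()
  providers <- list()
  for (p in catalog$pathways) {
    covs <- lapply(reports, function(r) attr(r, "step_coverage")[[p$pathway_id]])
    cov_all <- do.call(rbind, covs)  # all genomes x steps
    step_cov <- apply(cov_all, 2, any)
    prov <- lapply(seq_along(p$steps),
                   function(s) unique(rownames(cov_all)[cov_all[, s]]))
    sole <- which(vapply(prov, function(x) length(x) == 1L, TRUE) &
                  step_cov)
    whitelisted <- vapply(p$steps,
                          function(alts) all(alts %in% whitelist), TRUE)
    rows[[p$pathway_id]] <- data.frame(
      pathway_id = p$pathway_id, class = p$class,
      covered_steps = sum(step_cov), total_steps = length(p$steps),
      union_completeness = mean(step_cov),
      jointly_complete = all(step_cov | whitelisted),
      n_sole_provider_steps = length(sole),
      stringsAsFactors = FALSE)
    rows[[p$pathway_id]]$sole_provider_steps <-
      I(list(vapply(p$steps[sole], paste, "", collapse = "/")))
    providers[[p$pathway_id]] <- prov
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("consortium_report", "data.frame"),
            providers = providers, whitelist = whitelist)
}
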