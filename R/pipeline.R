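# End-to-end pipeline: simulate (optional) -> split detection -> stop
# usage -> pathway complementarity -> pairwise comparisons, with a
# provenance record so every reported number is traceable.
#
# One config (YAML file or list) drives everything.  Output tables are
# TSV with fixed column orders; each carries the config checksum in a
# leading comment line, so re-running an identical config reproduces
# byte-identical files.

#' Validate a pipeline configuration
#'
#' Sections (all optional unless noted): \code{seed}; \code{simulate}
#' (a \code{\link{simulate_consortium}} config); \code{genomes} /
#' \code{features} (paths to FASTA and feature files, used when not
#' simulating); \code{splits} (\code{max_gap}, \code{min_half_length});
#' \code{pathways} (\code{catalog}, \code{presence_fixture},
#' \code{whitelist}, \code{consortia}: named lists of genome ids);
#' \code{compare} (\code{pairs}: list of 2-vectors of genome ids,
#' \code{fragment_length}, \code{anchor_k}).
#'
#' @param config path to a YAML file or a list
#' @return validated config list (class \code{pipeline_config})
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  for (p in c(config$genomes, config$features,
              config$pathways$catalog, config$pathways$presence_fixture)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  }
  sp <- config$splits
  if (!is.null(sp$max_gap) && sp$max_gap < 0) stop("max_gap must be >= 0")
  if (!is.null(sp$min_half_length) && sp$min_half_length < 1) {
    stop("min_half_length must be >= 1")
  }
  structure(config, class = c("pipeline_config", "list"))
}

.config_checksum <- function(config) {
  raw <- serialize(unclass(config)[order(names(unclass(config)))], NULL,
                   version = 2)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(raw, tmp)
  unname(tools::md5sum(tmp))
}

.write_stamped_tsv <- function(df, path, checksum) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# endosym config=%s", checksum), con)
  listcols <- vapply(df, is.list, TRUE)
  df[listcols] <- lapply(df[listcols], function(col)
    vapply(col, function(x) paste(unlist(x), collapse = ";"), ""))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages and writes a deterministic report
#' bundle under \code{out_dir}: simulated inputs (if any), merged-gene
#' annotation, stop-usage table, per-genome completeness and consortium
#' reports, comparison tables, a provenance JSON and a MANIFEST.  A stage
#' failure aborts with the stage named; outputs written so far stay on
#' disk and the MANIFEST records the bundle as incomplete.
#'
#' @param config a \code{\link{pipeline_config}} (or path / list)
#' @param out_dir output directory
#' @param quiet suppress progress messages
#' @return invisibly, a list with the in-memory results of each stage
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  config <- pipeline_config(config)
  checksum <- .config_checksum(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- character(0)
  results <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    .write_stamped_tsv(df, path, checksum)
    manifest <<- c(manifest, name)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(manifest, sprintf("INCOMPLETE at stage %s", name)),
                 file.path(out_dir, "MANIFEST"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  genomes <- list()
  feature_sets <- list()

  stage("inputs", {
    if (!is.null(config$simulate)) {
      sim_cfg <- config$simulate
      sim_cfg$seed <- sim_cfg$seed %||% config$seed
      sims <- simulate_consortium(sim_cfg)
      for (nm in names(sims)) {
        write_simulation(sims[[nm]], file.path(out_dir, "simulated"))
        genomes[[nm]] <- sims[[nm]]$genome
        feature_sets[[nm]] <- sims[[nm]]$features
      }
      results$simulations <- sims
      say("simulated %d genome(s)", length(sims))
    }
    if (!is.null(config$genomes)) {
      for (path in config$genomes) {
        for (g in read_fasta(path)) genomes[[g$id]] <- g
      }
    }
    if (!is.null(config$features)) {
      for (path in config$features) {
        dialect <- if (grepl("\\.gff3?$", path)) "gff3"
          else if (grepl("\\.(gb|gbk|gbff)$", path)) "genbank" else "tsv"
        fs <- read_features(path, dialect, genomes = genomes)
        for (gid in unique(fs$genome_id)) {
          feature_sets[[gid]] <- new_feature_set(
            fs[fs$genome_id == gid, , drop = FALSE], source = dialect)
        }
      }
    }
    say("loaded %d genome(s), %d feature set(s)",
        length(genomes), length(feature_sets))
  })

  merged_all <- NULL
  stage("splits", {
    if (length(feature_sets)) {
      cands <- list()
      usage <- list()
      for (gid in names(feature_sets)) {
        if (!gid %in% names(genomes)) next
        cc <- find_split_candidates(
          genomes[[gid]], feature_sets[[gid]],
          max_gap = config$splits$max_gap %||% 30L,
          min_half_length = config$splits$min_half_length %||% 10L)
        cands[[gid]] <- cc
        u <- stop_usage(genomes[[gid]], feature_sets[[gid]], cc)
        u <- cbind(genome_id = gid, u)
        usage[[gid]] <- u
        say("%s: %d CDS, %d split candidate(s)", gid,
            sum(feature_sets[[gid]]$type == "CDS" &
                feature_sets[[gid]]$segment == 1L), nrow(cc))
      }
      merged_all <- do.call(rbind, lapply(cands, write_merged_annotation))
      emit(merged_all %||% data.frame(), "merged_annotation.tsv")
      emit(do.call(rbind, usage), "stop_usage.tsv")
      results$split_candidates <- cands
      results$stop_usage <- usage
    }
  })

  stage("pathways", {
    pw <- config$pathways
    if (!is.null(pw)) {
      catalog <- if (!is.null(pw$catalog)) load_catalog(pw$catalog)
                 else load_catalog()
      presence <- if (!is.null(pw$presence_fixture)) {
        read_presence(pw$presence_fixture, catalog)
      } else if (length(feature_sets)) {
        all_feats <- do.call(rbind, lapply(feature_sets, as.data.frame))
        profile_presence(new_feature_set(all_feats), merged_all, catalog)
      } else NULL
      if (!is.null(presence)) {
        comp <- completeness(presence, catalog)
        emit(comp, "completeness.tsv")
        results$completeness <- comp
        whitelist <- pw$whitelist %||% DEFAULT_WHITELIST
        consortia <- pw$consortia %||%
          list(all = rownames(presence))
        cons_out <- list()
        for (nm in names(consortia)) {
          members <- intersect(consortia[[nm]], rownames(presence))
          sub <- completeness(
            presence[members, , drop = FALSE], catalog)
          cons <- consortium_union(sub, whitelist = whitelist,
                                   catalog = catalog)
          cons_out[[nm]] <- cons
          emit(cbind(consortium = nm, cons),
               sprintf("consortium_%s.tsv", nm))
          say("consortium %s: %d/%d pathways jointly complete", nm,
              sum(cons$jointly_complete), nrow(cons))
        }
        results$consortium <- cons_out
      }
    }
  })

  stage("compare", {
    cmp <- config$compare
    if (!is.null(cmp$pairs)) {
      rows <- list()
      for (pair in cmp$pairs) {
        a <- genomes[[pair[[1]]]]; b <- genomes[[pair[[2]]]]
        if (is.null(a) || is.null(b)) {
          stop("compare pair references unknown genome: ",
               paste(unlist(pair), collapse = ","))
        }
        snp <- count_snps(a, b, anchor_k = cmp$anchor_k %||% 17L)
        an <- tryCatch(
          ani(a, b, fragment_length = cmp$fragment_length %||% 1020L),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_a = a$id, genome_b = b$id,
          n_substitutions = snp$n_substitutions,
          n_indel_events = snp$n_indel_events,
          rotation_offset = snp$rotation_offset,
          ani_percent = if (is.null(an)) NA_real_ else
            round_half_up(an$ani_percent, 2),
          stringsAsFactors = FALSE)
      }
      emit(do.call(rbind, rows), "comparisons.tsv")
      results$comparisons <- do.call(rbind, rows)
    }
    if (length(genomes)) {
      stats <- do.call(rbind, lapply(names(genomes), function(gid) {
        genome_stats(genomes[[gid]], feature_sets[[gid]])
      }))
      emit(stats, "genome_stats.tsv")
      results$genome_stats <- stats
    }
  })

  stage("provenance", {
    prov <- list(
      package = "endosym",
      version = as.character(utils::packageVersion("endosym")),
      seed = config$seed,
      config_checksum = checksum,
      parameters = unclass(config),
      input_checksums = local({
        paths <- unlist(c(config$genomes, config$features,
                          config$pathways$catalog,
                          config$pathways$presence_fixture))
        if (length(paths)) as.list(tools::md5sum(paths)) else list()
      })
    )
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- c(manifest, "provenance.json")
    writeLines(c(manifest, "COMPLETE"), file.path(out_dir, "MANIFEST"))
  })

  invisible(results)
}
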