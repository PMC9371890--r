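#' Default pipeline configuration
#'
#' Every parameter of the end-to-end synthetic run with its default. The
#' same structure, as YAML, is accepted by [validate_config()].
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 17L,
    stages = c("simulate", "consensus", "annotate", "spectrum", "junctions"),
    genotypes = c("WT-like", "DA-like", "KO-like"),
    germline = list(length = 294L, gc_fraction = 0.5),
    repertoire = list(n_clones = 150L, inherited_fraction = 0.2,
                      mean_clone_size = 2),
    reads = list(umi_length = 8L, reads_per_molecule = 3L,
                 error_rate = 0.001, read_length = 180L),
    consensus = list(min_overlap = 20L, max_mismatch_frac = 0.1,
                     min_family_size = 1L),
    annotate = list(max_mismatch_frac = 0.15),
    spectrum = list(n_iterations = 1000L, alpha = 0.05),
    junctions = list(n_per_genotype = 40L, anchor_min = 10L)
  )
}

.merge_defaults <- function(user, defaults) {
  if (!is.list(user)) return(defaults)
  for (k in names(defaults)) {
    user[[k]] <- if (is.list(defaults[[k]]) && !is.null(user[[k]])) {
      .merge_defaults(user[[k]], defaults[[k]])
    } else if (is.null(user[[k]])) defaults[[k]] else user[[k]]
  }
  user
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, a YAML string, or a list; applies defaults for
#' every omitted field and checks every constraint, reporting all
#' violations at once rather than stopping at the first.
#'
#' @param x Config source (`NULL` means all defaults).
#' @return A validated `run_config` list.
#' @export
validate_config <- function(x = NULL) {
  raw <- if (is.null(x)) {
    list()
  } else if (is.list(x)) {
    x
  } else if (file.exists(x)) {
    yaml::read_yaml(x)
  } else {
    yaml::yaml.load(x)
  }
  if (is.null(raw)) raw <- list()
  cfg <- .merge_defaults(raw, default_config())

  problems <- character(0)
  check <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)

  check(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed) &&
          abs(cfg$seed) < 2^30, "seed must be an integer below 2^30")
  known_stages <- default_config()$stages
  check(all(cfg$stages %in% known_stages),
        paste("unknown stage(s):",
              paste(setdiff(cfg$stages, known_stages), collapse = ", ")))
  check(all(cfg$genotypes %in% names(default_profiles())),
        paste("unknown genotype(s):",
              paste(setdiff(cfg$genotypes, names(default_profiles())),
                    collapse = ", ")))
  check(cfg$germline$length >= 30, "germline length must be >= 30")
  check(cfg$germline$gc_fraction >= 0 && cfg$germline$gc_fraction <= 1,
        "gc_fraction must lie in [0,1]")
  check(cfg$repertoire$n_clones >= 1, "n_clones must be >= 1")
  check(cfg$repertoire$inherited_fraction >= 0 &&
          cfg$repertoire$inherited_fraction <= 1,
        "inherited_fraction must lie in [0,1]")
  check(cfg$reads$umi_length >= 4, "umi_length must be >= 4")
  check(cfg$reads$reads_per_molecule >= 1, "reads_per_molecule must be >= 1")
  check(cfg$reads$error_rate >= 0 && cfg$reads$error_rate < 1,
        "error_rate must lie in [0,1)")
  check(cfg$consensus$min_overlap >= 10, "min_overlap must be >= 10")
  check(cfg$consensus$min_family_size >= 1, "min_family_size must be >= 1")
  check(cfg$spectrum$n_iterations >= 1, "n_iterations must be >= 1")
  check(cfg$spectrum$alpha > 0 && cfg$spectrum$alpha < 1,
        "alpha must lie in (0,1)")
  check(cfg$junctions$n_per_genotype >= 2, "n_per_genotype must be >= 2")
  check(cfg$junctions$anchor_min >= 5, "anchor_min must be >= 5")

  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = "run_config")
}

.stage_seed <- function(seed, stage, geno_idx = 0L) {
  stage_idx <- match(stage, default_config()$stages)
  as.integer(seed + 1000L * stage_idx + geno_idx)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the selected stages — simulate, consensus, annotate, spectrum,
#' junctions — for every configured genotype, writing all tabular outputs
#' as TSV under `out_dir` plus a machine-readable JSON run summary. A
#' single top-level seed deterministically derives a seed per stage and
#' genotype, so identical configurations produce byte-identical outputs.
#' Rejected records are never dropped silently: every stage's report row
#' carries input/passed/rejected counts and rejection reasons are written
#' alongside the stage outputs.
#'
#' @param config Anything accepted by [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @return A `run_report` list: `stages` (data.frame of record counts),
#'   `seed`, `version` and the paths written.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("shmrun")) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- default_profiles()[cfg$genotypes]
  mixtures <- default_junction_mixtures()[cfg$genotypes]
  counts <- list()
  paths <- character(0)
  note <- function(stage, genotype, input, passed) {
    counts[[length(counts) + 1L]] <<- data.frame(
      stage = stage, genotype = genotype, input = input, passed = passed,
      rejected = input - passed, stringsAsFactors = FALSE)
  }
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    .write_tsv(df, p)
    paths <<- c(paths, p)
  }

  # pre-flight: stages that consume prior outputs from disk need them present
  missing <- character(0)
  for (g in cfg$genotypes) {
    slug <- gsub("[^A-Za-z0-9]+", "_", g)
    if ("consensus" %in% cfg$stages && !"simulate" %in% cfg$stages) {
      missing <- c(missing, Filter(Negate(file.exists), file.path(
        out_dir, paste0(slug, c("_R1.fastq", "_R2.fastq")))))
    }
    if ("annotate" %in% cfg$stages && !"consensus" %in% cfg$stages) {
      missing <- c(missing, Filter(Negate(file.exists), file.path(
        out_dir, paste0(slug, "_consensus.fasta"))))
    }
    if ("spectrum" %in% cfg$stages && !"annotate" %in% cfg$stages) {
      stop("the spectrum stage requires the annotate stage in the same run")
    }
  }
  if (length(missing)) {
    stop("missing inputs for selected stages:\n  ",
         paste(missing, collapse = "\n  "))
  }

  germline <- make_germline(cfg$germline$length, cfg$germline$gc_fraction,
                            seed = .stage_seed(cfg$seed, "simulate"))
  write_germline(germline, file.path(out_dir, "germline.fasta"),
                 file.path(out_dir, "germline_regions.tsv"))

  annotated <- list(); spectra <- list(); scores <- list()
  for (gi in seq_along(cfg$genotypes)) {
    g <- cfg$genotypes[gi]
    slug <- gsub("[^A-Za-z0-9]+", "_", g)

    if ("simulate" %in% cfg$stages) {
      p_geom <- 1 / cfg$repertoire$mean_clone_size
      rep_sim <- simulate_repertoire(
        germline, profiles[[g]], n_clones = cfg$repertoire$n_clones,
        clone_size_dist = function(n) 1L + rgeom(n, prob = p_geom),
        inherited_fraction = cfg$repertoire$inherited_fraction,
        seed = .stage_seed(cfg$seed, "simulate", gi))
      reads <- simulate_reads(
        rep_sim$sequences, umi_length = cfg$reads$umi_length,
        reads_per_molecule = cfg$reads$reads_per_molecule,
        error_rate = cfg$reads$error_rate,
        read_length = cfg$reads$read_length,
        min_overlap = cfg$consensus$min_overlap,
        seed = .stage_seed(cfg$seed, "simulate", gi) + 500L)
      write_fastq_pairs(reads$reads,
                        file.path(out_dir, paste0(slug, "_R1.fastq")),
                        file.path(out_dir, paste0(slug, "_R2.fastq")))
      emit(rep_sim$truth$mutations, paste0(slug, "_truth_mutations.tsv"))
      emit(reads$umi_map, paste0(slug, "_umi_map.tsv"))
      note("simulate", g, length(rep_sim$sequences), length(rep_sim$sequences))
    } else {
      reads <- list(reads = read_fastq_pairs(
        file.path(out_dir, paste0(slug, "_R1.fastq")),
        file.path(out_dir, paste0(slug, "_R2.fastq"))))
    }

    if ("consensus" %in% cfg$stages) {
      col <- collapse_reads(reads$reads, umi_length = cfg$reads$umi_length,
                            min_overlap = cfg$consensus$min_overlap,
                            max_mismatch_frac = cfg$consensus$max_mismatch_frac,
                            min_family_size = cfg$consensus$min_family_size)
      write_consensus_fasta(col$consensus,
                            file.path(out_dir, paste0(slug, "_consensus.fasta")))
      if (nrow(col$rejected_pairs) || nrow(col$rejected_families)) {
        rej <- rbind(
          data.frame(record = col$rejected_pairs$read_id,
                     reason = col$rejected_pairs$reason),
          data.frame(record = col$rejected_families$umi,
                     reason = col$rejected_families$reason))
        emit(rej, paste0(slug, "_consensus_rejects.tsv"))
      }
      note("consensus", g, nrow(reads$reads),
           sum(col$consensus$family_size))
    }

    if ("annotate" %in% cfg$stages) {
      if (!"consensus" %in% cfg$stages) {
        col <- list(consensus = read_consensus_fasta(
          file.path(out_dir, paste0(slug, "_consensus.fasta"))))
      }
      ann <- annotate_repertoire(col$consensus, germline,
                                 max_mismatch_frac = cfg$annotate$max_mismatch_frac)
      grp <- group_clones(ann$sequences)
      annotated[[g]] <- list(sequences = grp$sequences,
                             mutations = ann$mutations)
      emit(ann$mutations, paste0(slug, "_mutations.tsv"))
      emit(grp$clones, paste0(slug, "_clones.tsv"))
      note("annotate", g, nrow(col$consensus), nrow(grp$sequences))
    }

    if ("spectrum" %in% cfg$stages) {
      sc <- spectrum_config(cfg$spectrum$n_iterations,
                            seed = .stage_seed(cfg$seed, "spectrum", gi),
                            alpha = cfg$spectrum$alpha)
      spec <- aggregate_spectrum(annotated[[g]], germline, sc)
      spectra[[g]] <- spec
      emit(spec$summary, paste0(slug, "_spectrum.tsv"))
      emit(spec$positional, paste0(slug, "_positional.tsv"))
      note("spectrum", g, nrow(annotated[[g]]$sequences),
           nrow(annotated[[g]]$sequences))
    }

    if ("junctions" %in% cfg$stages) {
      jct <- simulate_junctions(mixtures[[g]], cfg$junctions$n_per_genotype,
                                seed = .stage_seed(cfg$seed, "junctions", gi),
                                anchor_min = cfg$junctions$anchor_min)
      write_fasta(jct$junctions, file.path(out_dir, paste0(slug, "_junctions.fasta")))
      sj <- score_junctions(jct$junctions, jct$donor, jct$acceptor,
                            anchor_min = cfg$junctions$anchor_min)
      scores[[g]] <- sj$score[sj$resolved]
      emit(sj, paste0(slug, "_junction_scores.tsv"))
      note("junctions", g, length(jct$junctions), sum(sj$resolved))
    }
  }

  if ("spectrum" %in% cfg$stages && length(spectra) >= 2L) {
    ref <- cfg$genotypes[1L]
    contrasts <- do.call(rbind, lapply(cfg$genotypes[-1L], function(g) {
      ct <- compare_genotypes(spectra[[ref]], spectra[[g]])
      cbind(data.frame(reference = ref, genotype = g,
                       stringsAsFactors = FALSE), ct)
    }))
    emit(contrasts, "spectrum_contrasts.tsv")
  }

  if ("junctions" %in% cfg$stages && length(scores) >= 2L) {
    emit(do.call(rbind, lapply(names(scores), function(g)
      summarize_junction_cohort(scores[[g]], g))), "junction_cohorts.tsv")
    mh <- compare_mh_distributions(scores)
    pairs <- combn(names(scores), 2L, simplify = FALSE)
    fishers <- lapply(pairs, function(pr) {
      ft <- compare_insertion_frequencies(scores[[pr[1L]]], scores[[pr[2L]]])
      list(pair = paste(pr, collapse = " vs "), p_value = ft$p_value,
           odds_ratio = ft$odds_ratio)
    })
    jstats <- list(kruskal_wallis = list(H = mh$H, df = mh$df,
                                         p_value = mh$p_value),
                   dunn = mh$dunn, fisher_insertions = fishers)
    jpath <- file.path(out_dir, "junction_stats.json")
    jsonlite::write_json(jstats, jpath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    paths <- c(paths, jpath)
  }

  report <- list(stages = do.call(rbind, counts), seed = cfg$seed,
                 version = as.character(packageVersion("shmspectra")),
                 config = unclass(cfg), paths = paths)
  jsonlite::write_json(
    list(seed = report$seed, version = report$version,
         stages = report$stages, config = report$config),
    file.path(out_dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$seed, ", version", x$version, ")\n")
  print(x$stages)
  invisible(x)
}
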