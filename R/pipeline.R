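# End-to-end orchestration: one structured config drives simulation and the
# analysis stages, every output is listed in a checksum manifest, and
# re-running with the same config and inputs is byte-identical.

PIPELINE_STAGES <- c("simulate", "repeats", "recomb", "rearrange", "sweep",
                     "delcall")

#' Run the analysis pipeline
#'
#' Stages run in dependency order (`simulate` first when requested); each
#' stage reads only files in the output directory, so stages can also be
#' replayed individually against prior outputs. Inputs consumed by each
#' stage are checksummed; when a manifest from a previous run is present,
#' mismatching checksums abort the run.
#'
#' @param config path to a YAML config, or an equivalent named list.
#'   Recognised keys: `seed`, `outdir`, `stages`, and per-stage parameter
#'   blocks `simulate` (sim_config arguments), `repeats` (min_word,
#'   evalue_max), `recomb` (flank, min_identity), `sweep` (window, step,
#'   fst_min, ratio_min, maf_min, max_missing), `delcall` (threshold).
#'   Unknown keys are rejected.
#' @param outdir overrides the config's output directory
#' @return invisibly, the manifest data.frame
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("seed", "outdir", "stages", "simulate", "repeats", "recomb",
             "rearrange", "sweep", "delcall", "log_level")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(outdir)) outdir <- cfg$outdir
  if (is.null(outdir)) stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  stages <- if (is.null(cfg$stages)) PIPELINE_STAGES else cfg$stages
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]

  pth <- function(f) file.path(outdir, f)
  old_manifest <- NULL
  if (file.exists(pth("manifest.tsv"))) {
    old_manifest <- utils::read.delim(pth("manifest.tsv"),
                                      stringsAsFactors = FALSE)
  }
  need <- function(f, stage) {
    if (!file.exists(pth(f))) {
      stop("stage '", stage, "': missing upstream output '", f, "'")
    }
    if (!is.null(old_manifest) && f %in% old_manifest$file) {
      cur <- unname(tools::md5sum(pth(f)))
      rec <- old_manifest$md5[old_manifest$file == f][1L]
      if (!identical(cur, rec)) {
        stop("stage '", stage, "': checksum mismatch for input '", f,
             "' (file changed since it was produced)")
      }
    }
    pth(f)
  }
  manifest <- list()
  note <- function(f) manifest[[length(manifest) + 1L]] <<- f
  log_lines <- c("# mitostructkit pipeline run",
                 "# config:",
                 paste0("#   ", strsplit(yaml::as.yaml(cfg), "\n")[[1L]]))

  scfg <- do.call(sim_config, c(list(seed = seed), cfg$simulate))

  if ("simulate" %in% stages) {
    genome <- gen_circular_genome(scfg)
    write_fasta(stats::setNames(genome$seq, genome$id), pth("genome.fa"))
    write_repeats_tsv(genome$truth, pth("repeat_truth.tsv"))
    note("genome.fa"); note("repeat_truth.tsv")
    if (nrow(genome$truth)) {
      big <- genome$truth[which.max(genome$truth$length), ]
      rs <- sim_long_reads(genome, big, scfg)
      write_fasta(rs$reads, pth("reads.fa"))
      utils::write.table(rs$truth, pth("read_truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note("reads.fa"); note("read_truth.tsv")
    }
    rp <- gen_rearranged_pair(10L, scfg$n_inversions, seed = seed)
    write_block_orders(list(identity = rp$identity, scrambled = rp$scrambled),
                       pth("orders.tsv"))
    note("orders.tsv")
    pv <- gen_population_variants(scfg)
    write_vcf_haploid(pv$vm, pth("variants.vcf"))
    write_pop_map(pv$vm$pops, pth("pops.tsv"))
    note("variants.vcf"); note("pops.tsv")
    n_dep <- 24L
    truth <- rep(c(TRUE, FALSE), length.out = n_dep)
    dp <- gen_depth_profiles(scfg, n_dep, truth)
    write_depth_tsv(dp, pth("depth.tsv"))
    groups <- stats::setNames(rep(c("AW", "AC", "EW", "EC"),
                                  length.out = n_dep), dp$sample)
    write_pop_map(groups, pth("depth_groups.tsv"))
    note("depth.tsv"); note("depth_groups.tsv")
  }

  if ("repeats" %in% stages) {
    g <- read_fasta(need("genome.fa", "repeats"))[1L]
    pars <- cfg$repeats
    pairs <- find_repeats(g,
                          min_word = pars$min_word %||% 7L,
                          evalue_max = pars$evalue_max %||% 1e-6)
    write_repeats_tsv(pairs, pth("repeats.tsv"))
    write_repeats_bed(pairs, pth("repeats.bed"))
    note("repeats.tsv"); note("repeats.bed")
  }

  if ("recomb" %in% stages) {
    g <- read_fasta(need("genome.fa", "recomb"))[1L]
    reads <- read_fasta(need("reads.fa", "recomb"))
    pairs <- read_repeats_tsv(need("repeat_truth.tsv", "recomb"))
    pars <- cfg$recomb
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      p <- pairs[i, ]
      as_ <- tryCatch({
        a <- build_recombinant_references(g, p, flank = pars$flank %||% 200L)
        assign_reads(reads, a, min_identity = pars$min_identity %||% 99)
      }, error = function(e) NULL)
      if (is.null(as_)) return(NULL)
      data.frame(pair = i, class = p$class, n_ref = as_$n_ref,
                 n_recomb = as_$n_recomb,
                 n_uninformative = as_$n_uninformative,
                 frequency = as_$frequency, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    utils::write.table(tab, pth("recomb.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("recomb.tsv")
  }

  if ("rearrange" %in% stages) {
    orders <- read_block_orders(need("orders.tsv", "rearrange"))
    n <- length(orders)
    dm <- matrix(0L, n, n, dimnames = list(names(orders), names(orders)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j) {
        dm[i, j] <- dm[j, i] <-
          inversion_distance(perm_relative(orders[[j]], orders[[i]]))
      }
    }
    utils::write.table(dm, pth("distance_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    note("distance_matrix.tsv")
  }

  if ("sweep" %in% stages) {
    pops <- read_pop_map(need("pops.tsv", "sweep"))
    vm <- read_vcf_haploid(need("variants.vcf", "sweep"), pops)
    pars <- cfg$sweep
    vm <- filter_variants(vm, maf_min = pars$maf_min %||% 0.01,
                          max_missing = pars$max_missing %||% 0.1)
    ws <- window_stats(vm, window = pars$window %||% 1000L,
                       step = pars$step %||% 500L,
                       fst_min = pars$fst_min %||% 0.1,
                       ratio_min = pars$ratio_min %||% 2.0)
    utils::write.table(ws, pth("windows.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    regions <- call_sweeps(ws, fst_min = pars$fst_min %||% 0.1,
                           ratio_min = pars$ratio_min %||% 2.0,
                           ref_len = vm$ref_len)
    utils::write.table(regions, pth("sweeps.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("windows.tsv"); note("sweeps.tsv")
  }

  if ("delcall" %in% stages) {
    dp <- read_depth_tsv(need("depth.tsv", "delcall"))
    pars <- cfg$delcall
    calls <- data.frame(
      sample = dp$sample, Idep = dp$Idep, Wdep = dp$Wdep,
      ratio = dp$Idep / dp$Wdep,
      call = classify_presence(dp$Idep / dp$Wdep,
                               threshold = pars$threshold %||% 2.0),
      stringsAsFactors = FALSE)
    utils::write.table(calls, pth("calls.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("calls.tsv")
    if (file.exists(pth("depth_groups.tsv"))) {
      groups <- read_pop_map(need("depth_groups.tsv", "delcall"))
      ct <- carrier_frequencies(stats::setNames(calls$call, calls$sample),
                                groups)
      utils::write.table(ct$per_group, pth("carriers.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note("carriers.tsv")
    }
  }

  files <- unlist(manifest)
  man <- data.frame(file = files,
                    md5 = unname(tools::md5sum(file.path(outdir, files))),
                    stringsAsFactors = FALSE)
  if (!is.null(old_manifest)) {
    prev <- old_manifest[!(old_manifest$file %in% man$file) &
                           file.exists(file.path(outdir, old_manifest$file)), ,
                         drop = FALSE]
    man <- rbind(prev, man)
  }
  utils::write.table(man, pth("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(log_lines, pth("run.log"))
  invisible(man)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
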