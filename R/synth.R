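#' Specification for a synthetic scRNA-seq dataset with planted stress
#'
#' Describes a negative-binomial count model of several cell programs (cell
#' types) with a stressed state overlaid on every program: stressed cells
#' multiply the expression rate of the designated stress-set genes by
#' `exp(stress_lfc)` and of the lineage marker sets by
#' `exp(-lineage_depletion_lfc)`, emulating the characteristic combination
#' of elevated glycolysis/ER-stress programs and depleted neuro-/gliogenesis
#' programs. Marker sets are disjoint by construction.
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param n_programs number of cell programs (>= 2).
#' @param fraction_stressed planted stressed fraction in `[0, 1)`.
#' @param stress_lfc natural-log fold elevation of the two stress sets in
#'   stressed cells.
#' @param lineage_depletion_lfc natural-log fold depletion of lineage marker
#'   sets in stressed cells.
#' @param program_lfc natural-log fold elevation of a program's own markers.
#' @param n_marker genes per marker set (each stress set and each program).
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param base_sdlog log-normal spread of per-gene base rates.
#' @param seed random seed.
#' @return a validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_cells = 20000, n_genes = 2000, n_programs = 4,
                       fraction_stressed = 0.15, stress_lfc = 1.5,
                       lineage_depletion_lfc = 1, program_lfc = 1.5,
                       n_marker = 50, libsize_meanlog = log(3000),
                       libsize_sdlog = 0.35, dispersion = 0.3,
                       base_sdlog = 1.5, seed = 1) {
  spec <- list(n_cells = n_cells, n_genes = n_genes, n_programs = n_programs,
               fraction_stressed = fraction_stressed,
               stress_lfc = stress_lfc,
               lineage_depletion_lfc = lineage_depletion_lfc,
               program_lfc = program_lfc, n_marker = n_marker,
               libsize_meanlog = libsize_meanlog,
               libsize_sdlog = libsize_sdlog, dispersion = dispersion,
               base_sdlog = base_sdlog, seed = seed)
  stopifnot(spec$fraction_stressed >= 0, spec$fraction_stressed < 1,
            spec$n_programs >= 2, spec$n_cells >= 1, spec$n_genes >= 1,
            spec$dispersion > 0, spec$libsize_sdlog >= 0, spec$n_marker >= 1)
  # two stress sets + one lineage set per program, all disjoint
  if ((2 + spec$n_programs) * spec$n_marker > spec$n_genes)
    stop("synth_spec: marker sets need ", (2 + spec$n_programs) *
           spec$n_marker, " genes but n_genes = ", spec$n_genes,
         call. = FALSE)
  structure(spec, class = "synth_spec")
}

#' Generate a synthetic dataset from a specification
#'
#' Counts are drawn per cell from a negative binomial with mean
#' `libsize * rate / sum(rate)`, where the per-gene rate combines a
#' log-normal base rate, the cell's program-marker elevation, and — for
#' stressed cells — stress-set elevation and lineage-set depletion. Two
#' stress sets ("glycolysis"- and "ER-stress"-like) are planted, plus one
#' lineage marker set per program; the first two program sets double as the
#' "neurogenesis" / "gliogenesis" negative-filter sets. Deterministic per
#' seed.
#'
#' @param spec a [synth_spec()].
#' @return a list of class `synth_data`: `counts` (cells x genes sparse
#'   matrix), `truth` (data.frame with `cell_id`, `program`, `stressed`),
#'   and `sets` (named list of [gene_set()]: `glycolysis`, `er_stress`
#'   positive; `neurogenesis`, `gliogenesis` negative).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  g <- spec$n_genes
  k <- spec$n_marker
  genes <- sprintf("G%05d", seq_len(g))
  cells <- sprintf("cell%06d", seq_len(n))

  # disjoint marker blocks at the front of the gene list
  idx <- function(b) ((b - 1) * k + 1):(b * k)
  stress1 <- idx(1); stress2 <- idx(2)
  program_idx <- lapply(seq_len(spec$n_programs), function(p) idx(2 + p))

  base <- rlnorm(g, meanlog = 0, sdlog = spec$base_sdlog)

  program <- sample.int(spec$n_programs, n, replace = TRUE)
  n_stressed <- round(spec$fraction_stressed * n)
  stressed <- rep(FALSE, n)
  if (n_stressed > 0) stressed[sample.int(n, n_stressed)] <- TRUE

  # one expression profile per (program, stressed) state
  profiles <- list()
  for (p in seq_len(spec$n_programs)) for (st in c(FALSE, TRUE)) {
    r <- base
    r[program_idx[[p]]] <- r[program_idx[[p]]] * exp(spec$program_lfc)
    if (st) {
      r[c(stress1, stress2)] <- r[c(stress1, stress2)] * exp(spec$stress_lfc)
      for (q in program_idx)
        r[q] <- r[q] * exp(-spec$lineage_depletion_lfc)
    }
    profiles[[paste0(p, ".", st)]] <- r / sum(r)
  }

  libsize <- rlnorm(n, spec$libsize_meanlog, spec$libsize_sdlog)
  size <- 1 / spec$dispersion

  # draw in cell chunks, sparsifying as we go to bound memory
  prof_mat <- do.call(cbind, profiles)            # genes x states
  state <- paste0(program, ".", stressed)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 2000))
  parts <- lapply(chunks, function(rows) {
    mu <- t(prof_mat[, state[rows], drop = FALSE]) * libsize[rows]
    cnt <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                  nrow = length(rows))
    methods::as(cnt, "CsparseMatrix")
  })
  counts <- do.call(rbind, parts)
  dimnames(counts) <- list(cells, genes)

  sets <- list(
    glycolysis = gene_set("glycolysis", genes[stress1], "positive"),
    er_stress = gene_set("er_stress", genes[stress2], "positive"),
    neurogenesis = gene_set("neurogenesis", genes[program_idx[[1]]],
                            "negative"),
    gliogenesis = gene_set("gliogenesis", genes[program_idx[[2]]],
                           "negative"))

  structure(list(
    counts = count_matrix(counts),
    truth = data.frame(cell_id = cells, program = program,
                       stressed = stressed, stringsAsFactors = FALSE),
    sets = sets, spec = spec), class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf(paste0("<synth_data> %d cells x %d genes, %d programs, ",
                     "%.1f%% stressed\n"),
              nrow(x$counts), ncol(x$counts), x$spec$n_programs,
              100 * mean(x$truth$stressed)))
  invisible(x)
}

#' The canonical synthetic test dataset
#'
#' 20,000 cells, 2,000 genes, 4 programs, 15% planted stressed cells with a
#' stress elevation of 1.5 natural-log units — a stressed fraction close to
#' typical organoid observations.
#'
#' @param seed random seed.
#' @param n_cells override the cell count (the model is otherwise unchanged).
#' @return a `synth_data` bundle, see [synth_generate()].
#' @export
default_fixture <- function(seed = 1, n_cells = 20000) {
  synth_generate(synth_spec(n_cells = n_cells, seed = seed))
}

#' Write a synthetic dataset to disk
#'
#' Materializes the 10x-convention MTX directory, the ground-truth TSV
#' (`truth.tsv`) and the planted gene sets (`sets.gmt`) so the pipeline can
#' be exercised exactly as on real data.
#'
#' @param sd a `synth_data` bundle.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_synth <- function(sd, dir) {
  stopifnot(inherits(sd, "synth_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_10x_mtx(sd$counts, file.path(dir, "mtx"))
  write.table(sd$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gmt(sd$sets, file.path(dir, "sets.gmt"))
  invisible(dir)
}
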