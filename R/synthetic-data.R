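# Synthetic-data generators: toy genomes, planted essDNA regions with
# dose-dependent P1 cutting, mitochondrial strand-displacement termini, and
# tag-structured reads/alignments with recorded ground truth. Every
# downstream stage of the package is testable against these fixtures
# without external downloads.

#' Dose labels of the P1 titration design
#'
#' @return `c("control", "0.01U", "0.1U", "1U", "10U")`.
#' @export
titration_doses <- function() c("control", "0.01U", "0.1U", "1U", "10U")

#' Generate a toy genome
#'
#' Deterministic pseudo-random sequences at the requested GC content, with
#' optional planted homopolymer tracts (for internal-priming-filter tests).
#'
#' @param contig_sizes Named vector of contig lengths (>= 1 kb each).
#' @param gc GC content of the random background.
#' @param seed RNG seed.
#' @param tracts Optional data.frame with columns `contig`, `start`
#'   (0-based), `length`, `base`; each tract overwrites the sequence with a
#'   homopolymer run.
#' @return A `DNAStringSet`; the contig-length table is available via
#'   [genome_of()].
#' @export
make_toy_genome <- function(contig_sizes, gc = 0.4, seed = 1L,
                            tracts = NULL) {
  stopifnot(!is.null(names(contig_sizes)), all(contig_sizes >= 1000))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed_(seed, {
    vapply(as.integer(contig_sizes), function(n) {
      paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
    }, "")
  })
  names(seqs) <- names(contig_sizes)
  if (!is.null(tracts)) {
    for (i in seq_len(nrow(tracts))) {
      ctg <- tracts$contig[i]
      s <- tracts$start[i]
      l <- tracts$length[i]
      substr(seqs[[ctg]], s + 1, s + l) <-
        strrep(tracts$base[i], l)
    }
  }
  DNAStringSet(seqs)
}

#' Plant non-overlapping truth regions
#'
#' Places `n` regions of the requested sizes uniformly at random without
#' overlap (and with a minimum separation), recording the ground truth used
#' by recovery tests.
#'
#' @param genome Named contig-length vector.
#' @param n Number of regions.
#' @param sizes Region sizes: a scalar, a vector recycled to `n`, or a
#'   function of `n` returning sizes (e.g. a log-normal sampler).
#' @param seed RNG seed.
#' @param label Class label stored in the `name` column.
#' @param min_gap Minimum separation between planted regions in bp.
#' @param avoid Optional `GRanges` the regions must not overlap.
#' @return A `GRanges` truth set with a `name` metadata column.
#' @export
plant_regions <- function(genome, n = 20L, sizes = 200L, seed = 1L,
                          label = "essDNA", min_gap = 1000L, avoid = NULL) {
  with_seed_(seed, {
    sz <- if (is.function(sizes)) round(sizes(n)) else
      rep_len(round(sizes), n)
    sz <- pmax(sz, 1)
    placed_ctg <- character(0)
    placed_s <- numeric(0)
    placed_e <- numeric(0)
    taken <- if (is.null(avoid)) GRanges() else
      GRanges(seqnames(avoid), IRanges(start(avoid), end(avoid)))
    tries <- 0L
    for (i in seq_len(n)) {
      repeat {
        tries <- tries + 1L
        if (tries > 1000L * n) {
          stop("could not pack ", n, " regions into the genome")
        }
        ci <- sample.int(length(genome), 1, prob = as.numeric(genome))
        len <- as.numeric(genome)[ci]
        if (len < sz[i]) next
        s <- floor(runif(1) * (len - sz[i]))
        cand <- GRanges(names(genome)[ci],
                        IRanges(max(s - min_gap, 0) + 1,
                                min(s + sz[i] + min_gap, len)))
        if (length(taken) > 0 &&
            sum(countOverlaps(cand, taken)) > 0) next
        placed_ctg <- c(placed_ctg, names(genome)[ci])
        placed_s <- c(placed_s, s)
        placed_e <- c(placed_e, s + sz[i])
        taken <- c(taken, GRanges(names(genome)[ci],
                                  IRanges(s + 1, s + sz[i])))
        break
      }
    }
    interval_set(placed_ctg, placed_s, placed_e,
                 label = rep(label, n), genome = genome)
  })
}

#' P1 titration model
#'
#' Rates are termini per bp. The background single-strand-break rate is
#' dose-independent; the specific rate applies inside planted regions of
#' each class and encodes the dose response (rising with dose, saturating,
#' then collapsing at the over-digesting top dose as the exposed essDNA is
#' degraded); the nonspecific rate is the genome-wide double-stranded
#' cutting that becomes visible only at the top dose. Default in-region cut
#' density at 0.1U (0.10 termini/bp, i.e. ~20 expected cuts in a 200 bp
#' region) mirrors the cluster density observed in called essDNA regions
#' (about 5 sites per 40-50 bp).
#'
#' @param background_rate Background SSB terminus rate per bp (default
#'   0.0005, i.e. 0.5 sites/kb).
#' @param specific_density Named list: class label -> named vector of
#'   per-dose in-region cut rates (termini/bp). Must be 0 for `control`.
#' @param nonspecific_rate Named per-dose vector of genome-wide P1 cut
#'   rates; 0 for `control`.
#' @return A list of class `titration_model`.
#' @export
titration_model <- function(
    background_rate = 5e-4,
    specific_density = list(
      essDNA = c(control = 0, "0.01U" = 0.03, "0.1U" = 0.10,
                 "1U" = 0.12, "10U" = 0.03)),
    nonspecific_rate = c(control = 0, "0.01U" = 0, "0.1U" = 0,
                         "1U" = 2.5e-4, "10U" = 4e-3)) {
  doses <- titration_doses()
  stopifnot(background_rate >= 0, all(nonspecific_rate >= 0),
            setequal(names(nonspecific_rate), doses))
  for (cl in names(specific_density)) {
    v <- specific_density[[cl]]
    stopifnot(setequal(names(v), doses), all(v >= 0))
    if (v[["control"]] != 0) stop("specific rate must be 0 in the control")
  }
  if (nonspecific_rate[["control"]] != 0) {
    stop("nonspecific rate must be 0 in the control")
  }
  structure(list(background_rate = background_rate,
                 specific_density = specific_density,
                 nonspecific_rate = nonspecific_rate),
            class = "titration_model")
}

uniform_sites_ <- function(n, genome) {
  if (n == 0) {
    return(data.frame(contig = character(), position = numeric(),
                      strand = character()))
  }
  ci <- sample.int(length(genome), n, replace = TRUE,
                   prob = as.numeric(genome))
  len <- as.numeric(genome)[ci]
  data.frame(contig = names(genome)[ci],
             position = pmin(floor(runif(n) * len), len - 1),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate a terminus titration series over planted regions
#'
#' Produces one [terminus_table] per dose: Poisson background everywhere,
#' plus Poisson in-region P1 cuts at the class- and dose-specific rate,
#' plus genome-wide nonspecific cuts at the top doses. Deterministic per
#' seed.
#'
#' @param truth Planted truth `GRanges` (from [plant_regions()]); its
#'   `name` column selects the class in `model$specific_density`.
#' @param genome Named contig-length vector.
#' @param model A [titration_model()].
#' @param seed RNG seed.
#' @param sample_prefix Prefix for the per-dose sample ids.
#' @return Named list of [terminus_table]s, one per dose label.
#' @export
simulate_titration_termini <- function(truth, genome,
                                       model = titration_model(),
                                       seed = 1L,
                                       sample_prefix = "sim") {
  gl <- sum(as.numeric(genome))
  cls <- if (length(truth) > 0 && !is.null(mcols(truth)$name)) {
    mcols(truth)$name
  } else {
    rep(names(model$specific_density)[1], length(truth))
  }
  with_seed_(seed, {
    out <- list()
    for (dose in titration_doses()) {
      n_bg <- rpois(1, model$background_rate * gl)
      df <- uniform_sites_(n_bg, genome)
      for (i in seq_along(truth)) {
        rate <- model$specific_density[[cls[i]]][[dose]]
        if (is.null(rate)) stop("no specific rate for class ", cls[i])
        wdt <- width(truth)[i]
        n_sp <- rpois(1, rate * wdt)
        if (n_sp > 0) {
          pos <- start(truth)[i] - 1 + floor(runif(n_sp) * wdt)
          df <- rbind(df, data.frame(
            contig = as.character(seqnames(truth))[i],
            position = pos,
            strand = sample(c("+", "-"), n_sp, replace = TRUE),
            stringsAsFactors = FALSE))
        }
      }
      n_ns <- rpois(1, model$nonspecific_rate[[dose]] * gl)
      df <- rbind(df, uniform_sites_(n_ns, genome))
      out[[dose]] <- terminus_table(
        df$contig, df$position, df$strand,
        sample_id = paste(sample_prefix, dose, sep = "_"),
        dose_label = dose)
    }
    out
  })
}

#' Mitochondrial strand-displacement simulation model
#'
#' Relative single-stranded exposure times per region of the heavy strand
#' (defaults encode the strand-displacement expectations Q1 > Q2 and
#' Q3 > Q4), a uniform low exposure of the light strand, a background SSB
#' weight shared by all positions, and the P1 signal strength per unit
#' exposure. The total P1 signal is kept modest relative to the background
#' so the essDNA index of the unexposed light strand stays near 1 (the
#' index normalizes by total mitochondrial termini, so a dominant treated
#' signal would depress it). An optional 7S-DNA-like site places redundant
#' termini at one fixed heavy-strand position in the NCR in every sample,
#' including the untreated control.
#'
#' @param h_exposure Named relative exposures of the heavy strand per
#'   region.
#' @param l_exposure Uniform relative exposure of the light strand.
#' @param background Background SSB weight per bp (both strands).
#' @param p1_strength P1 weight per bp per unit exposure at dose multiplier
#'   1.
#' @param dose_response Named per-dose multiplier of `p1_strength`; peaks
#'   at 1U and collapses at 10U, following the titration behaviour.
#' @param seven_s_position 0-based heavy-strand NCR position of the 7S-like
#'   site.
#' @param seven_s_weight Sampling weight of the 7S-like site, in bp
#'   equivalents of background (0 disables it).
#' @return A list of class `mito_sim_model`.
#' @export
mito_sim_model <- function(
    h_exposure = c(Q1 = 1.0, Q2 = 0.45, Q3 = 0.8, Q4 = 0.35,
                   NCR = 0.5, OL = 0.5),
    l_exposure = 0.02, background = 1, p1_strength = 0.6,
    dose_response = c(control = 0, "0.01U" = 0.25, "0.1U" = 1,
                      "1U" = 1.25, "10U" = 0.4),
    seven_s_position = 190L, seven_s_weight = 0) {
  stopifnot(all(h_exposure >= 0), l_exposure >= 0, background > 0,
            p1_strength >= 0, dose_response[["control"]] == 0,
            seven_s_weight >= 0)
  structure(list(h_exposure = h_exposure, l_exposure = l_exposure,
                 background = background, p1_strength = p1_strength,
                 dose_response = dose_response,
                 seven_s_position = as.integer(seven_s_position),
                 seven_s_weight = seven_s_weight),
            class = "mito_sim_model")
}

#' Simulate mitochondrial termini under strand displacement
#'
#' Allocates `n` termini per dose multinomially across (region, strand)
#' cells with weight `length x (background + p1_strength x dose x
#' exposure)`, uniform positions within each (possibly wrapped) region.
#'
#' @param model A [mito_sim_model()].
#' @param anno A [mito_annotation()].
#' @param n Termini per sample.
#' @param seed RNG seed.
#' @return Named list of [terminus_table]s, one per dose label.
#' @export
simulate_mito_termini <- function(model = mito_sim_model(),
                                  anno = mito_annotation(), n = 50000L,
                                  seed = 1L) {
  cells <- list()
  for (region in mito_region_names(anno)) {
    m <- anno$regions[[region]]
    for (r in seq_len(nrow(m))) {
      for (strand in c("H", "L")) {
        expo <- if (strand == "H") model$h_exposure[[region]] else
          model$l_exposure
        cells[[length(cells) + 1L]] <- list(
          start = m[r, "start"], end = m[r, "end"],
          ref_strand = mito_ref_strand(anno, strand), exposure = expo)
      }
    }
  }
  len <- vapply(cells, function(c) c$end - c$start, 0)
  expo <- vapply(cells, `[[`, 0, "exposure")
  with_seed_(seed, {
    out <- list()
    for (dose in titration_doses()) {
      mult <- model$dose_response[[dose]]
      wts <- len * (model$background + model$p1_strength * mult * expo)
      if (model$seven_s_weight > 0) {
        wts <- c(wts, model$seven_s_weight)
      }
      counts <- as.integer(rmultinom(1, n, wts))
      df <- data.frame(contig = character(), position = numeric(),
                       strand = character())
      for (i in seq_along(cells)) {
        if (counts[i] == 0) next
        pos <- cells[[i]]$start +
          floor(runif(counts[i]) * (cells[[i]]$end - cells[[i]]$start))
        df <- rbind(df, data.frame(contig = anno$contig, position = pos,
                                   strand = cells[[i]]$ref_strand,
                                   stringsAsFactors = FALSE))
      }
      if (model$seven_s_weight > 0 && counts[length(counts)] > 0) {
        df <- rbind(df, data.frame(
          contig = anno$contig,
          position = rep(model$seven_s_position,
                         counts[length(counts)]),
          strand = mito_ref_strand(anno, "H"),
          stringsAsFactors = FALSE))
      }
      out[[dose]] <- terminus_table(df$contig, df$position, df$strand,
                                    sample_id = paste0("mito_", dose),
                                    dose_label = dose)
    }
    out
  })
}

#' Emit tag-structured reads and alignments for planted termini
#'
#' For every terminus (with multiplicity) a read pair is written: read 1 is
#' a 9-11 G anchor plus inert filler, read 2 is an 11-13 T anchor followed
#' by the reverse complement of up to `read_len` bases of the broken strand
#' ending at the 3'-OH. Matching read-2 SAM records (correct contig,
#' strand, position) are emitted so terminus extraction can be tested
#' without running an aligner; termini close to a contig edge yield
#' shortened but still valid reads.
#'
#' Termini whose first sequenced genomic base is a T are tag-ambiguous:
#' the polyT anchor absorbs adjacent genomic Ts, so their position cannot
#' be recovered exactly by any downstream pipeline. Such termini are not
#' emitted; they are returned with `emitted = FALSE`.
#'
#' @param truth A [terminus_table] of planted termini.
#' @param genome A `DNAStringSet`.
#' @param fastq1,fastq2,sam Output paths (any may be `NULL` to skip).
#' @param seed RNG seed for the anchor lengths and filler.
#' @param read_len Maximum genomic bases carried by read 2.
#' @param filler_len Length of the inert read-1 filler.
#' @return Invisibly, the expected-terminus table: data.frame with `qname`
#'   (`NA` for non-emitted termini), `contig`, `position`, `strand`,
#'   `aln_strand`, `aln_start`, `aln_end`, `emitted`.
#' @export
emit_reads <- function(truth, genome, fastq1 = NULL, fastq2 = NULL,
                       sam = NULL, seed = 1L, read_len = 100L,
                       filler_len = 50L) {
  stopifnot(is_terminus_table(truth), is(genome, "DNAStringSet"))
  glen <- genome_of(genome)
  idx <- rep(seq_len(nrow(truth)), truth$count)
  n <- length(idx)
  with_seed_(seed, {
    g_runs <- sample(9:11, n, replace = TRUE)
    t_runs <- sample(11:13, n, replace = TRUE)
    # inert filler; its first base must not extend the G anchor
    fillers <- vapply(seq_len(n), function(i) {
      paste(c(sample(c("A", "C", "T"), 1),
              sample(c("A", "C", "G", "T"), filler_len - 1,
                     replace = TRUE)), collapse = "")
    }, "")
    ctg <- truth$contig[idx]
    pos <- truth$position[idx]
    str <- truth$strand[idx]
    plus_aln <- str == "-"  # read 2 aligns + when the broken strand is -
    L <- ifelse(plus_aln, pmin(read_len, glen[ctg] - pos),
                pmin(read_len, pos + 1))
    aln_start <- ifelse(plus_aln, pos, pos - L + 1)
    aln_end <- aln_start + L
    ref_seq <- character(n)
    for (ct in unique(ctg)) {
      sel <- ctg == ct
      v <- extractAt(genome[[ct]], IRanges(aln_start[sel] + 1,
                                           aln_end[sel]))
      ref_seq[sel] <- as.character(v)
    }
    read2_core <- ifelse(plus_aln, ref_seq,
                         as.character(reverseComplement(
                           DNAStringSet(ref_seq))))
    emitted <- substr(read2_core, 1, 1) != "T"
    qname <- rep(NA_character_, n)
    qname[emitted] <- sprintf("t%06d", seq_len(sum(emitted)))
    e <- emitted
    r1 <- paste0(strrep("G", g_runs[e]), fillers[e])
    r2 <- paste0(strrep("T", t_runs[e]), read2_core[e])
    if (!is.null(fastq1)) {
      write_fastq_(qname[e], r1, strrep("I", nchar(r1)), fastq1)
    }
    if (!is.null(fastq2)) {
      write_fastq_(qname[e], r2, strrep("I", nchar(r2)), fastq2)
    }
    if (!is.null(sam)) {
      hdr <- c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(glen), glen))
      flag <- ifelse(plus_aln[e], 129L, 145L)
      rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                     qname[e], flag, ctg[e], aln_start[e] + 1, L[e],
                     ref_seq[e], strrep("I", nchar(ref_seq[e])))
      writeLines(c(hdr, rec), sam)
    }
    invisible(data.frame(qname = qname, contig = ctg, position = pos,
                         strand = str,
                         aln_strand = ifelse(plus_aln, "+", "-"),
                         aln_start = aln_start, aln_end = aln_end,
                         emitted = emitted,
                         stringsAsFactors = FALSE))
  })
}

#' Build interval sets with a prescribed overlap structure
#'
#' Generic "tower" construction for multi-set overlap fixtures: each tower
#' is one genomic locus holding one interval from each member set (all
#' mutually overlapping); unique intervals get loci of their own. The
#' resulting sets reproduce exactly the requested per-set unique counts and
#' cross-set overlap counts.
#'
#' @param patterns Data.frame with columns `pattern` (set names joined by
#'   `&`, e.g. `"A&B"`) and `count` (towers of that composition).
#' @param unique_counts Named vector: intervals per set overlapping no
#'   other set.
#' @param width Interval width in bp.
#' @param spacing Distance between consecutive loci (must exceed `width`).
#' @param contig Contig name.
#' @return List with `sets` (named list of `GRanges`) and `genome` (named
#'   length-1 contig vector).
#' @export
make_overlap_towers <- function(patterns, unique_counts, width = 100L,
                                spacing = 1000L, contig = "vennSim") {
  stopifnot(spacing > width)
  members <- strsplit(patterns$pattern, "&", fixed = TRUE)
  set_names <- union(unlist(members), names(unique_counts))
  starts <- setNames(vector("list", length(set_names)), set_names)
  locus <- 0L
  for (i in seq_len(nrow(patterns))) {
    cnt <- patterns$count[i]
    if (cnt == 0) next
    pos <- (locus + seq_len(cnt) - 1) * spacing
    for (s in members[[i]]) starts[[s]] <- c(starts[[s]], pos)
    locus <- locus + cnt
  }
  for (s in names(unique_counts)) {
    cnt <- unique_counts[[s]]
    if (cnt == 0) next
    pos <- (locus + seq_len(cnt) - 1) * spacing
    starts[[s]] <- c(starts[[s]], pos)
    locus <- locus + cnt
  }
  glen <- setNames(max(1000, locus * spacing + width), contig)
  sets <- lapply(starts, function(p) {
    if (length(p) == 0) return(GRanges())
    interval_set(contig, p, p + width, genome = glen)
  })
  list(sets = sets, genome = glen)
}

#' Build a promoter/TSS/CAGE proximity fixture
#'
#' Promoters are laid out on a spaced grid; promoters flagged proximal get
#' a TSS at their midpoint, and proximal promoters additionally flagged
#' CAGE-supported get a CAGE peak covering that TSS. Spacing is large
#' relative to the radius so proximity is controlled exactly by the flags.
#'
#' @param is_proximal Logical vector, one element per promoter.
#' @param is_cage_proximal Logical vector (`TRUE` implies proximal).
#' @param radius Proximity radius the fixture is built for.
#' @param width Promoter width.
#' @param spacing Grid spacing (> `2 * (radius + width)`).
#' @param contig Contig name.
#' @return List with `promoters` (`GRanges`), `tss` ([tss_records]),
#'   `cage` (`GRanges`), `genome`.
#' @export
make_promoter_tss_fixture <- function(is_proximal, is_cage_proximal,
                                      radius = 1000L, width = 200L,
                                      spacing = 10000L,
                                      contig = "promSim") {
  n <- length(is_proximal)
  stopifnot(length(is_cage_proximal) == n,
            !any(is_cage_proximal & !is_proximal),
            spacing > 2 * (radius + width))
  pstart <- (seq_len(n) - 1) * spacing + radius + width
  glen <- setNames(n * spacing + 2 * (radius + width), contig)
  promoters <- interval_set(contig, pstart, pstart + width,
                            label = sprintf("P%06d", seq_len(n)),
                            genome = glen)
  tpos <- pstart[is_proximal] + floor(width / 2)
  tss <- tss_records(contig, tpos, "+",
                     sprintf("g%06d", which(is_proximal)))
  cage_pos <- pstart[is_cage_proximal] + floor(width / 2)
  cage <- if (length(cage_pos) > 0) {
    interval_set(contig, cage_pos, cage_pos + 1, genome = glen)
  } else {
    GRanges()
  }
  list(promoters = promoters, tss = tss, cage = cage, genome = glen)
}
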