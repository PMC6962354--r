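#' Read a PAF mapping file into mapping records
#'
#' Parses the 12 mandatory tab-separated PAF columns plus the optional
#' `tp:A:` tag; records without the tag are treated as primary.
#'
#' @param path path to a PAF file (plain text).
#' @return a data.frame of mapping records with columns `read_id`,
#'   `read_length`, `chrom`, `start`, `end` (0-based half-open target
#'   span), `matched_bases`, `mapq`, `is_primary`, `strand`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(empty_mappings())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 12))
    stop("malformed PAF line ", which(n < 12)[1], ": fewer than 12 columns")
  get <- function(i) vapply(fields, `[[`, "", i)
  tp <- vapply(fields, function(f) {
    tag <- grep("^tp:A:", f[-(1:12)], value = TRUE)
    if (length(tag)) substring(tag[1], 6, 6) else "P"
  }, "")
  data.frame(
    read_id = get(1),
    read_length = as.numeric(get(2)),
    chrom = get(6),
    start = as.numeric(get(8)),
    end = as.numeric(get(9)),
    matched_bases = as.numeric(get(10)),
    mapq = as.integer(get(12)),
    is_primary = tp == "P",
    strand = get(5),
    stringsAsFactors = FALSE)
}

#' @rdname read_paf
#' @param records mapping-record data.frame (see [read_paf()] for columns).
#' @param model a [genome_model()] supplying target lengths.
#' @export
write_paf <- function(records, path, model) {
  stopifnot(inherits(model, "genome_model"))
  if (nrow(records) == 0) { file.create(path); return(invisible(path)) }
  tlen <- stats::setNames(model$chromosomes$length, model$chromosomes$name)
  out <- data.frame(
    q = records$read_id, ql = format_bp(records$read_length),
    qs = 0, qe = format_bp(records$end - records$start),
    st = records$strand, t = records$chrom,
    tl = format_bp(tlen[records$chrom]),
    ts = format_bp(records$start), te = format_bp(records$end),
    nm = format_bp(records$matched_bases),
    ab = format_bp(records$end - records$start),
    mq = records$mapq,
    tp = ifelse(records$is_primary, "tp:A:P", "tp:A:S"))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

empty_mappings <- function() {
  data.frame(read_id = character(0), read_length = numeric(0),
             chrom = character(0), start = numeric(0), end = numeric(0),
             matched_bases = numeric(0), mapq = integer(0),
             is_primary = logical(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' @param path 3+-column BED (0-based half-open).
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  df <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  out
}

# ---- structural-variant callsets ----

empty_calls <- function() {
  data.frame(id = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), svtype = character(0), length = numeric(0),
             precise = logical(0), source = character(0),
             stringsAsFactors = FALSE)
}

validate_calls <- function(calls) {
  span <- calls$svtype %in% c("DEL", "DUP", "INV")
  stopifnot(all(calls$length > 0),
            all(calls$end[span] - calls$start[span] == calls$length[span]),
            all(calls$end[calls$svtype == "INS"] == calls$start[calls$svtype == "INS"]))
  calls
}

#' Read a read-based caller's SV VCF
#'
#' Expects VCF 4.2 with `SVTYPE`, `SVLEN` and `END` INFO keys and
#' `PRECISE`/`IMPRECISE` flags (the dialect written by read-based callers
#' such as Sniffles). Breakpoint-type records (`BND`/`TRA`) are dropped.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param source label stored in the `source` column (default the file
#'   name).
#' @return SV call data.frame: `id`, `chrom`, `start`, `end` (0-based
#'   half-open; `end == start` for insertions), `svtype`, `length`,
#'   `precise`, `source`.
#' @export
read_sv_vcf <- function(path, source = basename(path)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix)) || nrow(fix) == 0) return(empty_calls())
  info <- fix[, "INFO"]
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    hit <- regexpr(paste0("(^|;)", key, "=[^;]+"), info) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  svtype <- grab("SVTYPE")
  svlen <- abs(as.numeric(grab("SVLEN")))
  precise <- grepl("(^|;)PRECISE($|;)", info)
  pos <- as.numeric(fix[, "POS"])
  keep <- svtype %in% c("INS", "DEL", "DUP", "INV")
  start <- pos - 1
  end <- ifelse(svtype == "INS", start, start + svlen)
  calls <- data.frame(
    id = as.character(fix[, "ID"]), chrom = as.character(fix[, "CHROM"]),
    start = start, end = end, svtype = svtype, length = svlen,
    precise = precise, source = source, stringsAsFactors = FALSE)[keep, ]
  rownames(calls) <- NULL
  validate_calls(calls)
}

#' @rdname read_sv_vcf
#' @param calls SV call data.frame.
#' @param model a [genome_model()] for contig header lines.
#' @export
write_sv_vcf <- function(calls, path, model) {
  stopifnot(inherits(model, "genome_model"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=chromsort",
    sprintf("##contig=<ID=%s,length=%s>", model$chromosomes$name,
            format_bp(model$chromosomes$length)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Precise breakpoints\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) == 0) { writeLines(hdr, path); return(invisible(path)) }
  svlen <- ifelse(calls$svtype == "DEL", -calls$length, calls$length)
  end1 <- ifelse(calls$svtype == "INS", calls$start + 1, calls$end)
  info <- sprintf("%s;SVTYPE=%s;SVLEN=%s;END=%s",
                  ifelse(calls$precise, "PRECISE", "IMPRECISE"),
                  calls$svtype, format_bp(svlen), format_bp(end1))
  rows <- sprintf("%s\t%s\t%s\tN\t<%s>\t.\tPASS\t%s",
                  calls$chrom, format_bp(calls$start + 1), calls$id,
                  calls$svtype, info)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read/write an Assemblytics-style SV BED
#'
#' Columns: chrom, start, stop, id, size, strand, type, with types
#' `Insertion`, `Deletion`, `Repeat_expansion`, `Repeat_contraction`,
#' `Tandem_expansion`, `Tandem_contraction`. Expansions are mapped to
#' `INS` and contractions to `DEL` so the two callers' types are
#' comparable; assembly-based calls are treated as precise.
#'
#' @param path BED path.
#' @param source label for the `source` column.
#' @return SV call data.frame (see [read_sv_vcf()]).
#' @export
read_assemblytics_bed <- function(path, source = basename(path)) {
  df <- read_bed_raw(path, 7)
  if (nrow(df) == 0) return(empty_calls())
  type_map <- c(Insertion = "INS", Deletion = "DEL",
                Repeat_expansion = "INS", Repeat_contraction = "DEL",
                Tandem_expansion = "INS", Tandem_contraction = "DEL")
  svtype <- type_map[as.character(df[[7]])]
  if (anyNA(svtype))
    stop("unknown Assemblytics type: ",
         paste(unique(df[[7]][is.na(svtype)]), collapse = ", "))
  start <- as.numeric(df[[2]])
  size <- as.numeric(df[[5]])
  calls <- data.frame(
    id = as.character(df[[4]]), chrom = as.character(df[[1]]),
    start = start,
    end = ifelse(svtype == "INS", start, start + size),
    svtype = unname(svtype), length = size, precise = TRUE,
    source = source, stringsAsFactors = FALSE)
  validate_calls(calls)
}

read_bed_raw <- function(path, min_cols) {
  if (file.size(path) == 0) return(data.frame())
  df <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(df) < min_cols)
    stop(path, ": expected >= ", min_cols, " columns, found ", ncol(df))
  df
}

#' @rdname read_assemblytics_bed
#' @param calls SV call data.frame.
#' @export
write_assemblytics_bed <- function(calls, path) {
  if (nrow(calls) == 0) { file.create(path); return(invisible(path)) }
  type_map <- c(INS = "Insertion", DEL = "Deletion", DUP = "Repeat_expansion",
                INV = "Inversion")
  out <- data.frame(
    chrom = calls$chrom, start = format_bp(calls$start),
    stop = format_bp(ifelse(calls$svtype == "INS", calls$start + 1, calls$end)),
    id = calls$id, size = format_bp(calls$length), strand = "+",
    type = unname(type_map[calls$svtype]))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- assembly alignment blocks ----

empty_blocks <- function() {
  data.frame(query = character(0), qstart = numeric(0), qend = numeric(0),
             target = character(0), tstart = numeric(0), tend = numeric(0),
             identity = numeric(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Read assembly-to-reference alignment blocks
#'
#' `read_paf_blocks` reads blocks from PAF; `read_coords` reads the
#' nucmer `show-coords -T -H` tabular dialect (columns S1 E1 S2 E2 LEN1
#' LEN2 %IDY ref qry, 1-based inclusive; query coordinates reversed on
#' the minus strand).
#'
#' @param path input path.
#' @return block data.frame: `query`, `qstart`, `qend`, `target`,
#'   `tstart`, `tend` (0-based half-open), `identity` (fraction),
#'   `strand`.
#' @export
read_paf_blocks <- function(path) {
  rec <- read_paf(path)
  if (nrow(rec) == 0) return(empty_blocks())
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    query = rec$read_id,
    qstart = as.numeric(vapply(fields, `[[`, "", 3)),
    qend = as.numeric(vapply(fields, `[[`, "", 4)),
    target = rec$chrom, tstart = rec$start, tend = rec$end,
    identity = rec$matched_bases / pmax(1, rec$end - rec$start),
    strand = rec$strand, stringsAsFactors = FALSE)
}

#' @rdname read_paf_blocks
#' @export
read_coords <- function(path) {
  if (file.size(path) == 0) return(empty_blocks())
  df <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(df) < 9)
    stop(path, ": expected >= 9 columns of show-coords -T -H output")
  s2 <- as.numeric(df[[3]]); e2 <- as.numeric(df[[4]])
  rev <- s2 > e2
  data.frame(
    query = as.character(df[[9]]),
    qstart = ifelse(rev, e2, s2) - 1, qend = ifelse(rev, s2, e2),
    target = as.character(df[[8]]),
    tstart = as.numeric(df[[1]]) - 1, tend = as.numeric(df[[2]]),
    identity = as.numeric(df[[7]]) / 100,
    strand = ifelse(rev, "-", "+"), stringsAsFactors = FALSE)
}

#' @rdname read_paf_blocks
#' @param blocks block data.frame.
#' @export
write_coords <- function(blocks, path) {
  if (nrow(blocks) == 0) { file.create(path); return(invisible(path)) }
  rev <- blocks$strand == "-"
  out <- data.frame(
    s1 = format_bp(blocks$tstart + 1), e1 = format_bp(blocks$tend),
    s2 = format_bp(ifelse(rev, blocks$qend, blocks$qstart + 1)),
    e2 = format_bp(ifelse(rev, blocks$qstart + 1, blocks$qend)),
    len1 = format_bp(blocks$tend - blocks$tstart),
    len2 = format_bp(blocks$qend - blocks$qstart),
    idy = sprintf("%.2f", blocks$identity * 100),
    ref = blocks$target, qry = blocks$query)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- RepeatMasker .out ----

rm_out_header <- c(
  "   SW   perc perc perc  query     position in query              matching  repeat         position in repeat",
  "score   div. del. ins.  sequence  begin  end          (left)     repeat    class/family   begin  end  (left)   ID",
  "")

#' Read/write RepeatMasker .out annotation tables
#'
#' The `.out` dialect is whitespace-aligned with a 3-line header; the
#' second column carries the percent divergence of each hit to its repeat
#' consensus. `read_repeatmasker_out` returns hits with a `divergence`
#' column (fraction, not percent); transition/transversion proportions
#' are not present in `.out` and can instead be supplied through the
#' simplified TSV dialect of [read_repeat_tsv()].
#'
#' @param path file path.
#' @return data.frame of repeat hits: `chrom`, `start`, `end` (0-based
#'   half-open), `repeat_name`, `class_family`, `divergence` (fraction).
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), repeat_name = character(0),
                      class_family = character(0), divergence = numeric(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  n <- lengths(fields)
  if (any(n < 11))
    stop("malformed .out line ", which(n < 11)[1] + 3, ": fewer than 11 columns")
  get <- function(i) vapply(fields, `[[`, "", i)
  data.frame(
    chrom = get(5),
    start = as.numeric(get(6)) - 1,  # .out is 1-based inclusive
    end = as.numeric(get(7)),
    repeat_name = get(10), class_family = get(11),
    divergence = as.numeric(get(2)) / 100,
    stringsAsFactors = FALSE)
}

#' @rdname read_repeatmasker_out
#' @param hits repeat-hit data.frame with a `divergence` column
#'   (fraction) or `p`/`q` columns (converted through
#'   [k2p_divergence()]).
#' @export
write_repeatmasker_out <- function(hits, path) {
  if (nrow(hits) == 0) { writeLines(rm_out_header, path); return(invisible(path)) }
  div <- if (!is.null(hits$divergence)) hits$divergence
         else k2p_divergence(hits$p, hits$q)
  rows <- sprintf(
    "%5d %6.2f %4.1f %4.1f  %s %10d %10d (%d) + %s %s %d %d (0) %d",
    1000L + seq_len(nrow(hits)) %% 9000L, div * 100, 0, 0,
    hits$chrom, as.integer(hits$start + 1), as.integer(hits$end), 0L,
    hits$repeat_name, hits$class_family, 1L, as.integer(hits$end - hits$start),
    seq_len(nrow(hits)))
  writeLines(c(rm_out_header, rows), path)
  invisible(path)
}

#' Read/write the simplified repeat TSV dialect carrying p and q
#'
#' Tab-separated with header `chrom start end repeat_name class_family p
#' q`: transition (`p`) and transversion (`q`) substitution proportions
#' per hit, from which the Kimura 2-parameter divergence is computed.
#'
#' @param path file path.
#' @return data.frame of repeat hits with `p` and `q` columns.
#' @export
read_repeat_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

#' @rdname read_repeat_tsv
#' @param hits repeat-hit data.frame.
#' @export
write_repeat_tsv <- function(hits, path) {
  data.table::fwrite(hits, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---- population genotype tables ----

#' Read a population SV genotype VCF plus superpopulation map
#'
#' @param vcf_path VCF with per-sample `GT` fields.
#' @param sample_map_path two-column TSV (sample, superpopulation), no
#'   header.
#' @return an [sv_genotype_table()].
#' @export
read_genotype_vcf <- function(vcf_path, sample_map_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  alleles <- strsplit(gt, "[/|]")
  counts <- vapply(alleles, function(a) {
    if (any(a == "." | is.na(a))) NA_integer_ else sum(a != "0")
  }, integer(1))
  dosage[] <- counts
  map <- data.table::fread(sample_map_path, sep = "\t", header = FALSE,
                           data.table = FALSE)
  superpop <- stats::setNames(as.character(map[[2]]), as.character(map[[1]]))
  variants <- data.frame(
    id = as.character(fix[, "ID"]), chrom = as.character(fix[, "CHROM"]),
    pos = as.numeric(fix[, "POS"]) - 1,
    n_alt_alleles = lengths(strsplit(as.character(fix[, "ALT"]), ",")),
    stringsAsFactors = FALSE)
  sv_genotype_table(variants, dosage, superpop)
}

#' @rdname read_genotype_vcf
#' @param table an [sv_genotype_table()].
#' @param path output VCF path.
#' @export
write_genotype_vcf <- function(table, path) {
  stopifnot(inherits(table, "sv_genotype_table"))
  v <- table$variants
  samples <- colnames(table$geno)
  hdr <- c("##fileformat=VCFv4.2", "##source=chromsort",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[table$geno + 1L],
                   nrow = nrow(table$geno))
  gt_str[is.na(table$geno)] <- "./."
  # multiallelic rows keep dosage semantics but list a second ALT allele
  alt <- ifelse(v$n_alt_alleles > 1,
                paste(rep("<INS>", 1), "<DEL>", sep = ","), "<INS>")
  rows <- paste(v$chrom, format_bp(v$pos + 1), v$id, "N", alt, ".", "PASS",
                ".", "GT", apply(gt_str, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
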