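#' Tokenize a transcript into word tokens and sentence spans
#'
#' Deterministic tokenization rule used throughout the pipeline: text is
#' lowercased; a token is a maximal run of letters/digits with optional
#' internal apostrophes (so "it's" is one token); every other character is a
#' separator. Sentences are split on runs of `.`, `!` or `?` followed by
#' whitespace or end of text; a transcript without terminal punctuation is a
#' single sentence. Dictionary-style word counting requires a fixed, documented
#' rule, which this is.
#'
#' @param raw_text A length-1 character vector (UTF-8).
#' @return A list with `tokens` (character vector of lowercase tokens) and
#'   `sentences`, a data.frame with columns `start`, `end`: 1-based inclusive
#'   token-index spans that partition the token vector in order. Empty text
#'   yields zero tokens and zero sentences.
#' @examples
#' tokenize("The boy is falling.")
#' tokenize("It's full. Yeah!")
#' @export
tokenize <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (is.na(raw_text)) raw_text <- ""
  txt <- tolower(raw_text)
  # normalize typographic apostrophes so contractions survive as one token
  txt <- gsub("’", "'", txt, fixed = TRUE)
  chunks <- strsplit(txt, "[.!?]+(\\s+|$)", perl = TRUE)[[1]]
  token_re <- "[\\p{L}\\p{N}]+(?:'[\\p{L}\\p{N}]+)*"
  tokens <- character(0)
  starts <- integer(0)
  ends <- integer(0)
  for (chunk in chunks) {
    tk <- regmatches(chunk, gregexpr(token_re, chunk, perl = TRUE))[[1]]
    if (length(tk) == 0L) next
    starts <- c(starts, length(tokens) + 1L)
    tokens <- c(tokens, tk)
    ends <- c(ends, length(tokens))
  }
  list(tokens = tokens,
       sentences = data.frame(start = starts, end = ends))
}

#' Construct a transcript object
#'
#' @param participant_id Participant identifier.
#' @param raw_text Raw transcript text.
#' @param language ISO-639-1 language code (default "en"). Non-English
#'   transcripts are accepted; the code is carried through to reports.
#' @return An object of class `transcript` with fields `participant_id`,
#'   `raw_text`, `language`, `tokens` and `sentences`.
#' @export
transcript <- function(participant_id, raw_text, language = "en") {
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            nzchar(participant_id))
  tk <- tokenize(raw_text)
  structure(
    list(participant_id = participant_id,
         raw_text = raw_text,
         language = language,
         tokens = tk$tokens,
         sentences = tk$sentences),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s: %d tokens, %d sentences, language %s>\n",
              x$participant_id, length(x$tokens), nrow(x$sentences),
              x$language))
  invisible(x)
}

cohort_metadata_columns <- c("participant_id", "age", "sex", "mmse",
                             "diagnosis", "split", "language")

validate_metadata <- function(meta) {
  missing_cols <- setdiff(cohort_metadata_columns, names(meta))
  if (length(missing_cols) > 0L)
    stop("metadata is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  dup <- meta$participant_id[duplicated(meta$participant_id)]
  if (length(dup) > 0L)
    stop("duplicate participant_id in metadata: ",
         paste(unique(dup), collapse = ", "))
  mmse <- meta$mmse
  bad <- !is.na(mmse) & (mmse < 0 | mmse > 30 | mmse != round(mmse))
  if (any(bad))
    stop("malformed mmse (must be integer in [0, 30]) for: ",
         paste(meta$participant_id[bad], collapse = ", "))
  bad_sex <- !is.na(meta$sex) & !meta$sex %in% c("male", "female")
  if (any(bad_sex))
    stop("sex must be 'male' or 'female' for: ",
         paste(meta$participant_id[bad_sex], collapse = ", "))
  bad_dx <- !is.na(meta$diagnosis) & !meta$diagnosis %in% c("CN", "ADRD")
  if (any(bad_dx))
    stop("diagnosis must be 'CN' or 'ADRD' for: ",
         paste(meta$participant_id[bad_dx], collapse = ", "))
  bad_split <- !meta$split %in% c("train", "test", "external")
  if (any(bad_split))
    stop("split must be one of train/test/external for: ",
         paste(meta$participant_id[bad_split], collapse = ", "))
  invisible(meta)
}

#' Read a transcript cohort from disk
#'
#' Reads the participant metadata CSV (columns
#' `participant_id,age,sex,mmse,diagnosis,split,language`) and, for each row,
#' the transcript file `<participant_id>.txt` in `transcript_dir`. Empty
#' `mmse` or `diagnosis` cells are parsed as missing values, never as zero.
#'
#' @param transcript_dir Directory holding one UTF-8 `.txt` file per
#'   participant.
#' @param metadata_path Path to the metadata CSV.
#' @return A list with `transcripts` (list of [transcript()] objects, metadata
#'   row order) and `metadata` (data.frame).
#' @export
read_cohort <- function(transcript_dir, metadata_path) {
  if (!dir.exists(transcript_dir))
    stop("transcript directory not found: ", transcript_dir)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_cols <- intersect(c("age", "mmse"), names(meta))
  for (cc in validate_cols) {
    v <- trimws(meta[[cc]])
    v[v == ""] <- NA_character_
    meta[[cc]] <- suppressWarnings(as.numeric(v))
  }
  for (cc in intersect(c("sex", "diagnosis", "split", "language"), names(meta))) {
    v <- trimws(meta[[cc]])
    v[v == ""] <- NA_character_
    meta[[cc]] <- v
  }
  validate_metadata(meta)
  paths <- file.path(transcript_dir, paste0(meta$participant_id, ".txt"))
  absent <- !file.exists(paths)
  if (any(absent))
    stop("transcript file missing for participant(s): ",
         paste(meta$participant_id[absent], collapse = ", "))
  transcripts <- lapply(seq_len(nrow(meta)), function(i) {
    txt <- paste(readLines(paths[i], encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    transcript(meta$participant_id[i], txt,
               language = ifelse(is.na(meta$language[i]), "en",
                                 meta$language[i]))
  })
  list(transcripts = transcripts, metadata = meta)
}

#' Write a cohort (transcripts + metadata) to disk
#'
#' Inverse of [read_cohort()]; used by the synthetic generator so that the
#' reader is exercised on generated corpora.
#'
#' @param cohort List with `transcripts` and `metadata` as from [read_cohort()].
#' @param dir Output directory (created if needed); transcripts go to
#'   `dir/transcripts/<id>.txt`, metadata to `dir/metadata.csv`.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  tdir <- file.path(dir, "transcripts")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  for (tr in cohort$transcripts) {
    writeLines(tr$raw_text, file.path(tdir, paste0(tr$participant_id, ".txt")),
               useBytes = TRUE)
  }
  mpath <- file.path(dir, "metadata.csv")
  utils::write.csv(cohort$metadata, mpath, row.names = FALSE, na = "")
  invisible(list(transcript_dir = tdir, metadata_path = mpath))
}

#' Load a category dictionary
#'
#' Dictionary format: UTF-8 text, one category per line as
#' `name: pattern1, pattern2, ...`; `#` starts a comment. A pattern is either
#' a literal token, a prefix pattern ending in `*` (matching any token that
#' starts with the stem), or a token bigram written with an underscore
#' (`you_know`). All patterns are lowercased on load; category order is file
#' order and fixes the feature-column order downstream.
#'
#' @param path Path to the dictionary file.
#' @return An object of class `category_dictionary`: list with `categories`
#'   (named list of pattern character vectors) and `category_order`.
#' @export
load_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cats <- list()
  for (ln in lines) {
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 1L) stop("malformed dictionary line (no ':'): ", ln)
    name <- trimws(substr(ln, 1L, colon - 1L))
    if (!nzchar(name)) stop("empty category name in dictionary line: ", ln)
    if (name %in% names(cats))
      stop("duplicate category name in dictionary: ", name)
    pats <- trimws(strsplit(substr(ln, colon + 1L, nchar(ln)), ",",
                            fixed = TRUE)[[1]])
    pats <- tolower(pats[nzchar(pats)])
    internal_star <- grepl("\\*.", pats)
    if (any(internal_star))
      stop("pattern with internal '*' in category '", name, "': ",
           paste(pats[internal_star], collapse = ", "))
    cats[[name]] <- pats
  }
  structure(list(categories = cats, category_order = names(cats)),
            class = "category_dictionary")
}

#' @export
print.category_dictionary <- function(x, ...) {
  cat(sprintf("<category_dictionary: %d categories, %d patterns>\n",
              length(x$category_order),
              sum(lengths(x$categories))))
  invisible(x)
}

#' Path to the bundled stand-in category dictionary
#'
#' The package ships an open, original 92-category dictionary with the same
#' mechanics as proprietary psycholinguistic dictionaries (literal tokens,
#' `*` prefix wildcards, underscore bigrams). Together with the five lexical
#' indices, words-per-sentence, the analytic composite and the disfluency
#' aggregate it yields the canonical 100-slot feature vector.
#'
#' @return Path to the installed dictionary file.
#' @export
standin_dictionary_path <- function() {
  system.file("extdata", "dictionary_standin.txt", package = "speechscreen",
              mustWork = TRUE)
}

#' Write / read a feature table
#'
#' CSV with `participant_id` first, then the 100 feature columns in canonical
#' order. Values are serialized with 17 significant digits so that a write /
#' read round trip is bit-exact.
#'
#' @param features Feature data.frame as from [extract_cohort_features()].
#' @param path Output CSV path.
#' @return `write_feature_table`: invisibly, `path`.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features), names(features)[1] == "participant_id")
  out <- features
  for (j in seq_along(out)[-1]) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = 1L)
  invisible(path)
}

#' @rdname write_feature_table
#' @return `read_feature_table`: the feature data.frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(df)[-1]) df[[j]] <- as.numeric(df[[j]])
  df
}
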