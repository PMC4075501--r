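#' @name record-store
#' @title Schema-less per-registry record storage
#'
#' @description
#' Patient data lives outside the definition metadata, in a schema-less
#' store: each captured field is a single key-value pair inside a
#' per-patient document, and each registry is isolated in its own
#' collection, so no sequence of writes through one registry can ever be
#' observed through another. Two interchangeable backends sit behind one
#' contract: an ephemeral in-memory store and an append-logged JSON-lines
#' file store (one UTF-8 file per collection, one full document state per
#' line, last-writer-wins on load). Uploaded files are content-addressed
#' blobs keyed by their SHA-256 digest.
NULL

file_value <- function(filename, digest, size) {
  structure(list(filename = filename, digest = digest, size = size),
            class = "regkit_file_value")
}

#' @export
print.regkit_file_value <- function(x, ...) {
  cat(sprintf("<file %s: %d bytes, sha256:%s>\n", x$filename, x$size,
              substr(x$digest, 1, 12)))
  invisible(x)
}

# ---- typed value <-> JSON-able encoding -----------------------------------

encode_typed_value <- function(tv) {
  v <- switch(tv$datatype,
    integer = tv$value,
    float   = tv$value,
    string  = tv$value,
    date    = format(tv$value, "%Y-%m-%d"),
    file    = list(filename = tv$value$filename, digest = tv$value$digest,
                   size = tv$value$size)
  )
  list(t = tv$datatype, v = v)
}

decode_typed_value <- function(de_code, enc) {
  v <- switch(enc$t,
    integer = as.numeric(enc$v),
    float   = as.numeric(enc$v),
    string  = as.character(enc$v),
    date    = as.Date(enc$v, format = "%Y-%m-%d"),
    file    = file_value(enc$v$filename, enc$v$digest, as.integer(enc$v$size))
  )
  typed_value(de_code, v, enc$t)
}

# ---- backends --------------------------------------------------------------
#
# A backend is a plain list of closures over private state:
#   get_doc(reg, pid) -> named list of encoded entries, or NULL
#   put_doc(reg, pid, entries), delete_doc(reg, pid)
#   list_pids(reg), registries()
#   put_blob(raw) -> digest, get_blob(digest) -> raw | NULL, delete_blob(digest)

memory_backend <- function() {
  cols <- new.env(parent = emptyenv())
  blobs <- new.env(parent = emptyenv())
  col_for <- function(reg, create = FALSE) {
    if (!exists(reg, envir = cols, inherits = FALSE)) {
      if (!create) return(NULL)
      assign(reg, new.env(parent = emptyenv()), envir = cols)
    }
    get(reg, envir = cols, inherits = FALSE)
  }
  list(
    kind = "memory",
    get_doc = function(reg, pid) {
      col <- col_for(reg)
      if (is.null(col) || !exists(pid, envir = col, inherits = FALSE)) return(NULL)
      get(pid, envir = col, inherits = FALSE)
    },
    put_doc = function(reg, pid, entries) {
      assign(pid, entries, envir = col_for(reg, create = TRUE))
    },
    delete_doc = function(reg, pid) {
      col <- col_for(reg)
      if (!is.null(col) && exists(pid, envir = col, inherits = FALSE)) {
        rm(list = pid, envir = col)
      }
    },
    list_pids = function(reg) {
      col <- col_for(reg)
      if (is.null(col)) character() else sort(ls(col))
    },
    registries = function() sort(ls(cols)),
    put_blob = function(raw) {
      dg <- digest::digest(raw, algo = "sha256", serialize = FALSE)
      assign(dg, raw, envir = blobs)
      dg
    },
    get_blob = function(dg) {
      if (exists(dg, envir = blobs, inherits = FALSE)) {
        get(dg, envir = blobs, inherits = FALSE)
      } else NULL
    },
    delete_blob = function(dg) {
      if (exists(dg, envir = blobs, inherits = FALSE)) rm(list = dg, envir = blobs)
    }
  )
}

file_backend <- function(dir) {
  col_dir <- file.path(dir, "collections")
  blob_dir <- file.path(dir, "blobs")
  dir.create(col_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(blob_dir, recursive = TRUE, showWarnings = FALSE)
  # in-memory image of each collection, replayed from its append log on
  # first touch; every mutation appends one line (entries = NULL tombstones)
  cache <- new.env(parent = emptyenv())
  col_path <- function(reg) {
    file.path(col_dir, paste0(utils::URLencode(reg, reserved = TRUE), ".jsonl"))
  }
  load_col <- function(reg) {
    if (exists(reg, envir = cache, inherits = FALSE)) {
      return(get(reg, envir = cache, inherits = FALSE))
    }
    col <- new.env(parent = emptyenv())
    path <- col_path(reg)
    if (file.exists(path)) {
      for (line in readLines(path, encoding = "UTF-8", warn = FALSE)) {
        if (!nzchar(line)) next
        rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
        if (is.null(rec$entries)) {
          if (exists(rec$patient_id, envir = col, inherits = FALSE)) {
            rm(list = rec$patient_id, envir = col)
          }
        } else {
          assign(rec$patient_id, rec$entries, envir = col)
        }
      }
    }
    assign(reg, col, envir = cache)
    col
  }
  append_line <- function(reg, rec) {
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
    cat(line, "\n", sep = "", file = col_path(reg), append = TRUE)
  }
  known_registries <- function() {
    files <- list.files(col_dir, pattern = "\\.jsonl$")
    on_disk <- vapply(files, function(f) {
      utils::URLdecode(sub("\\.jsonl$", "", f))
    }, character(1), USE.NAMES = FALSE)
    sort(unique(c(on_disk, ls(cache))))
  }
  list(
    kind = "file",
    get_doc = function(reg, pid) {
      col <- load_col(reg)
      if (!exists(pid, envir = col, inherits = FALSE)) return(NULL)
      get(pid, envir = col, inherits = FALSE)
    },
    put_doc = function(reg, pid, entries) {
      assign(pid, entries, envir = load_col(reg))
      append_line(reg, list(patient_id = pid, entries = entries))
    },
    delete_doc = function(reg, pid) {
      col <- load_col(reg)
      if (exists(pid, envir = col, inherits = FALSE)) {
        rm(list = pid, envir = col)
        append_line(reg, list(patient_id = pid, entries = NULL))
      }
    },
    list_pids = function(reg) sort(ls(load_col(reg))),
    registries = known_registries,
    put_blob = function(raw) {
      dg <- digest::digest(raw, algo = "sha256", serialize = FALSE)
      path <- file.path(blob_dir, dg)
      if (!file.exists(path)) writeBin(raw, path)
      dg
    },
    get_blob = function(dg) {
      path <- file.path(blob_dir, dg)
      if (!file.exists(path)) return(NULL)
      readBin(path, "raw", n = file.size(path))
    },
    delete_blob = function(dg) {
      path <- file.path(blob_dir, dg)
      if (file.exists(path)) unlink(path)
    }
  )
}

# ---- RecordStore -----------------------------------------------------------

RecordStore <- R6::R6Class("RecordStore",
  public = list(
    backend = NULL,

    initialize = function(backend = memory_backend()) {
      self$backend <- backend
    },

    # documents hold encoded entries; decode on the way out
    put = function(registry, patient_id, key, tv) {
      entries <- self$backend$get_doc(registry, patient_id) %||%
        structure(list(), names = character())
      entries[[key]] <- encode_typed_value(tv)
      self$backend$put_doc(registry, patient_id, entries)
      invisible(tv)
    },

    remove_key = function(registry, patient_id, key) {
      entries <- self$backend$get_doc(registry, patient_id)
      if (is.null(entries) || is.null(entries[[key]])) return(invisible(FALSE))
      entries[[key]] <- NULL
      self$backend$put_doc(registry, patient_id, entries)
      invisible(TRUE)
    },

    get = function(registry, patient_id, key) {
      entries <- self$backend$get_doc(registry, patient_id)
      if (is.null(entries) || is.null(entries[[key]])) return(NULL)
      decode_typed_value(decode_record_key(key)$de_code, entries[[key]])
    },

    # decoded document: named list key -> typed value
    doc = function(registry, patient_id) {
      entries <- self$backend$get_doc(registry, patient_id)
      if (is.null(entries)) return(NULL)
      out <- lapply(names(entries), function(k) {
        decode_typed_value(decode_record_key(k)$de_code, entries[[k]])
      })
      names(out) <- names(entries)
      out
    },

    has_patient = function(registry, patient_id) {
      !is.null(self$backend$get_doc(registry, patient_id))
    },

    register_patient = function(registry, patient_id) {
      if (!self$has_patient(registry, patient_id)) {
        self$backend$put_doc(registry, patient_id,
                             structure(list(), names = character()))
      }
      invisible(patient_id)
    },

    list_patients = function(registry) self$backend$list_pids(registry),

    delete_patient = function(registry, patient_id) {
      entries <- self$backend$get_doc(registry, patient_id)
      if (is.null(entries)) {
        regkit_warn(sprintf("patient '%s' not found in registry '%s'; nothing deleted",
                            patient_id, registry), "regkit_unknown_patient")
        return(invisible(FALSE))
      }
      digests <- unlist(lapply(entries, function(e) {
        if (identical(e$t, "file")) e$v$digest else NULL
      }), use.names = FALSE)
      self$backend$delete_doc(registry, patient_id)
      for (dg in unique(digests)) {
        if (!self$blob_referenced(dg)) self$backend$delete_blob(dg)
      }
      invisible(TRUE)
    },

    blob_referenced = function(dg) {
      for (reg in self$backend$registries()) {
        for (pid in self$backend$list_pids(reg)) {
          entries <- self$backend$get_doc(reg, pid)
          for (e in entries) {
            if (identical(e$t, "file") && identical(e$v$digest, dg)) return(TRUE)
          }
        }
      }
      FALSE
    },

    store_blob = function(raw) self$backend$put_blob(raw),

    fetch_blob = function(fv) {
      raw <- self$backend$get_blob(fv$digest)
      if (is.null(raw)) {
        regkit_abort(sprintf("stored file '%s' is missing its blob (sha256:%s)",
                             fv$filename, fv$digest), "regkit_missing_blob")
      }
      raw
    }
  )
)
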