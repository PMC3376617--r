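FRAME_HEAD <- as.raw(c(0x1B, 0x7E))
FRAME_END <- as.raw(0xFF)
FRAME_DATA_BYTES <- 512L
FRAME_BYTES <- 517L  # 2 head + 2 seq + 512 data + 1 end
ACK_BYTE <- as.raw(0x06)
NAK_BYTE <- as.raw(0x15)

#' Build one protocol frame
#'
#' A frame is 517 bytes: head `0x1B 0x7E`, a 16-bit big-endian sequence
#' number, exactly 512 data bytes, and the end byte `0xFF`.
#'
#' @param seq sequence number in `[0, 65535]`.
#' @param payload raw vector of at most 512 bytes; shorter payloads are
#'   zero-padded to 512.
#' @return A raw vector of length 517.
#' @export
make_frame <- function(seq, payload) {
  if (seq < 0 || seq > 65535)
    pp_error("pp_invalid_input", "sequence number must be in [0, 65535]")
  payload <- as.raw(payload)
  if (length(payload) > FRAME_DATA_BYTES)
    pp_error("pp_invalid_input", "payload exceeds 512 bytes")
  if (length(payload) < FRAME_DATA_BYTES)
    payload <- c(payload, raw(FRAME_DATA_BYTES - length(payload)))
  c(FRAME_HEAD, as.raw(c(seq %/% 256L, seq %% 256L)), payload, FRAME_END)
}

#' Parse and validate one serialized frame
#'
#' @param bytes raw vector of length 517.
#' @return A list with `seq` and `payload` (512 raw bytes).
#' @export
parse_frame <- function(bytes) {
  bytes <- as.raw(bytes)
  if (length(bytes) != FRAME_BYTES)
    pp_error("pp_framing_error",
             sprintf("frame must be %d bytes, got %d", FRAME_BYTES, length(bytes)))
  if (!identical(bytes[1:2], FRAME_HEAD))
    pp_error("pp_framing_error", "bad frame head bytes")
  if (!identical(bytes[FRAME_BYTES], FRAME_END))
    pp_error("pp_framing_error", "bad frame end byte")
  seq <- as.integer(bytes[3]) * 256L + as.integer(bytes[4])
  list(seq = seq, payload = bytes[5:(4 + FRAME_DATA_BYTES)])
}

#' Split a payload into protocol frames
#'
#' The payload is cut into 512-byte chunks (the final chunk zero-padded).
#' A leading length frame — 4-byte big-endian total payload length, then
#' zeros — precedes the data frames so the receiver can strip the padding
#' exactly. Sequence numbers run consecutively from 0 (the length frame),
#' wrapping at 65536.
#'
#' @param payload raw vector, length >= 1.
#' @return List of raw frames, each 517 bytes.
#' @export
packetize <- function(payload) {
  payload <- as.raw(payload)
  n <- length(payload)
  if (n == 0L) pp_error("pp_invalid_input", "empty payload")
  len_bytes <- as.raw(c(n %/% 16777216L, (n %/% 65536L) %% 256L,
                        (n %/% 256L) %% 256L, n %% 256L))
  n_chunks <- ceiling(n / FRAME_DATA_BYTES)
  frames <- vector("list", n_chunks + 1L)
  frames[[1L]] <- make_frame(0L, len_bytes)
  for (i in seq_len(n_chunks)) {
    from <- (i - 1L) * FRAME_DATA_BYTES + 1L
    frames[[i + 1L]] <- make_frame(i %% 65536L,
                                   payload[from:min(n, from + FRAME_DATA_BYTES - 1L)])
  }
  frames
}

#' Reassemble a payload from frames
#'
#' Validates head/end bytes and sequence continuity, reads the true length
#' from the leading length frame, concatenates the data frames, and strips
#' the zero padding. `depacketize(packetize(p))` is the identity.
#'
#' @param frames list of raw 517-byte frames in sequence order.
#' @return The original raw payload.
#' @export
depacketize <- function(frames) {
  if (length(frames) < 2L)
    pp_error("pp_framing_error", "need a length frame plus at least one data frame")
  parsed <- lapply(frames, parse_frame)
  seqs <- vapply(parsed, `[[`, integer(1), "seq")
  expected <- (seqs[1] + seq_along(seqs) - 1L) %% 65536L
  bad <- which(seqs != expected)
  if (length(bad) > 0L)
    pp_error("pp_framing_error",
             sprintf("sequence gap: expected seq %d, got %d",
                     expected[bad[1]], seqs[bad[1]]),
             missing_seq = expected[bad[1]])
  lenb <- as.integer(parsed[[1]]$payload[1:4])
  n <- ((lenb[1] * 256L + lenb[2]) * 256L + lenb[3]) * 256L + lenb[4]
  data <- do.call(c, lapply(parsed[-1], `[[`, "payload"))
  if (n > length(data))
    pp_error("pp_framing_error",
             sprintf("declared length %d exceeds %d received data bytes",
                     n, length(data)))
  data[seq_len(n)]
}

#' Lossy channel simulator
#'
#' A seeded test double for the wireless link: each transmitted frame draws
#' a reply that is silence (timeout) with probability `drop_prob`, an
#' erroneous reply (`0x15`) with probability `corrupt_prob`, and otherwise a
#' correct acknowledgement (`0x06`). Silence models a lost frame or lost
#' acknowledgement — the sender cannot distinguish the two.
#'
#' @param drop_prob,corrupt_prob probabilities in `[0, 1]`.
#' @param seed integer seed for the channel's own RNG stream.
#' @return A list of class `channel_model` with a `transmit(frame)` closure
#'   returning `"ack"`, `"timeout"` or `"error"`.
#' @export
channel_model <- function(drop_prob = 0, corrupt_prob = 0, seed = 1L) {
  stopifnot(drop_prob >= 0, drop_prob <= 1, corrupt_prob >= 0, corrupt_prob <= 1)
  rng <- local({
    state <- as.integer(seed)
    if (state == 0L) state <- 2147483587L  # xorshift has no zero state
    function() {
      # xorshift32, mapped to (0, 1); independent of R's RNG
      state <<- bitwXor(state, bitwShiftL(state, 13L))
      state <<- bitwXor(state, bitwShiftR(state, 17L))
      state <<- bitwXor(state, bitwShiftL(state, 5L))
      (state %% 1048576L + 1048576L) %% 1048576L / 1048576
    }
  })
  transmit <- function(frame) {
    u <- rng()
    if (u < drop_prob) return("timeout")
    if (u < drop_prob + (1 - drop_prob) * corrupt_prob) return("error")
    "ack"
  }
  structure(list(drop_prob = drop_prob, corrupt_prob = corrupt_prob,
                 seed = as.integer(seed), transmit = transmit),
            class = "channel_model")
}

#' Link configuration
#'
#' @param timeout nominal reply timeout in seconds (bookkeeping only in the
#'   simulator; no real waiting happens).
#' @param max_retries_before_reset consecutive timeouts on one frame before
#'   the link is reset and the same frame retried.
#' @param max_attempts_per_frame total transmission attempts allowed for a
#'   single frame before delivery is abandoned.
#' @return A list of class `link_config`.
#' @export
link_config <- function(timeout = 1.0, max_retries_before_reset = 5L,
                        max_attempts_per_frame = 50L) {
  stopifnot(timeout > 0, max_retries_before_reset >= 1,
            max_attempts_per_frame >= 1)
  structure(list(timeout = timeout,
                 max_retries_before_reset = as.integer(max_retries_before_reset),
                 max_attempts_per_frame = as.integer(max_attempts_per_frame)),
            class = "link_config")
}

#' Send frames over a lossy channel (stop-and-wait)
#'
#' One frame is in flight at a time. After sending, the sender waits for the
#' reply: on a correct acknowledgement it advances to the next frame; on a
#' timeout it retransmits the same frame; on an erroneous reply it resets
#' the connection and retransmits the same frame. Delivery of a frame is
#' abandoned — and the whole transfer fails — once its attempt budget is
#' exhausted.
#'
#' @param frames list of raw frames (e.g. from [packetize()]).
#' @param channel a [channel_model()].
#' @param cfg a [link_config()].
#' @return A list of class `transmission_log`: `delivered` (logical),
#'   `events` (data frame with columns `event`, `seq`, `attempt`), and
#'   counters `sends`, `retransmits`, `timeouts`, `resets`, `acks`.
#' @export
send_frames <- function(frames, channel, cfg = link_config()) {
  ev_event <- character(0); ev_seq <- integer(0); ev_attempt <- integer(0)
  log_ev <- function(e, s, a) {
    ev_event[[length(ev_event) + 1L]] <<- e
    ev_seq[[length(ev_seq) + 1L]] <<- s
    ev_attempt[[length(ev_attempt) + 1L]] <<- a
  }
  delivered <- TRUE
  sends <- 0L; resets <- 0L; frames_attempted <- 0L
  for (fr in frames) {
    frames_attempted <- frames_attempted + 1L
    seq <- parse_frame(fr)$seq
    attempt <- 0L
    consecutive_timeouts <- 0L
    acked <- FALSE
    while (!acked) {
      if (attempt >= cfg$max_attempts_per_frame) {
        log_ev("giveup", seq, attempt)
        delivered <- FALSE
        break
      }
      attempt <- attempt + 1L
      sends <- sends + 1L
      log_ev("send", seq, attempt)
      reply <- channel$transmit(fr)
      if (reply == "ack") {
        log_ev("ack", seq, attempt)
        acked <- TRUE
      } else if (reply == "timeout") {
        log_ev("timeout", seq, attempt)
        consecutive_timeouts <- consecutive_timeouts + 1L
        if (consecutive_timeouts >= cfg$max_retries_before_reset) {
          log_ev("reset", seq, attempt)
          resets <- resets + 1L
          consecutive_timeouts <- 0L
        }
      } else {  # erroneous reply: reset the module, reconnect, resend
        log_ev("error_reply", seq, attempt)
        log_ev("reset", seq, attempt)
        resets <- resets + 1L
        consecutive_timeouts <- 0L
      }
    }
    if (!acked) break  # stop-and-wait: never advance past an unacked frame
  }
  events <- data.frame(event = ev_event, seq = ev_seq, attempt = ev_attempt,
                       stringsAsFactors = FALSE)
  structure(list(
    delivered = delivered, events = events, sends = sends,
    retransmits = sends - frames_attempted,
    timeouts = sum(ev_event == "timeout"),
    resets = resets, acks = sum(ev_event == "ack")
  ), class = "transmission_log")
}

#' @export
print.transmission_log <- function(x, ...) {
  cat(sprintf("<transmission_log: %s; %d sends, %d retransmits, %d timeouts, %d resets>\n",
              if (x$delivered) "delivered" else "FAILED",
              x$sends, x$retransmits, x$timeouts, x$resets))
  invisible(x)
}

#' Write / read a frame stream to a file
#'
#' Frames are concatenated as fixed 517-byte records.
#'
#' @param frames list of raw frames.
#' @param path file path.
#' @return `write_frames` returns `path` invisibly; `read_frames` a list of
#'   raw frames.
#' @export
write_frames <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (fr in frames) writeBin(fr, con)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  if (!file.exists(path))
    pp_error("pp_io_error", sprintf("frame file not found: %s", path))
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) %% FRAME_BYTES != 0L)
    pp_error("pp_framing_error", "file size is not a multiple of 517 bytes")
  lapply(seq_len(length(bytes) %/% FRAME_BYTES), function(i)
    bytes[((i - 1L) * FRAME_BYTES + 1L):(i * FRAME_BYTES)])
}
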