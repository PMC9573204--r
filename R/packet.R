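# Wire-packet codec: a deterministic, testable stand-in for the Bluetooth
# stream between the glove mainboard and the host.
#
# Layout (little-endian, fixed 354 bytes):
#   bytes 1-4     seq    uint32  packet sequence number
#   bytes 5-8     t      int32   frame time, milliseconds
#   bytes 9-350   19 x 9 int16   IMU channels in channel_names() order
#   bytes 351-354 press  int32   pressure, or the NA sentinel (-2^31)
#
# Scales follow typical 16-bit IMU register conventions but use dyadic LSBs
# so quantisation is exact in binary floating point:
#   acc  1/2048 g      (+/- 16 g full scale)
#   gyro 1/16  deg/s   (+/- 2048 deg/s)
#   mag  1/4   uT      (+/- 8192 uT)
#   pressure 1/64 Pa   (int32)

PACKET_BYTES <- 354L

#' Quantisation step (LSB) of each packet field
#'
#' Values that are integer multiples of these steps survive
#' encode/decode exactly; anything else is rounded to the nearest step.
#' @return named list of LSB sizes: `acc` (g), `gyro` (deg/s), `mag` (uT),
#'   `pressure` (Pa), `t` (s)
#' @export
packet_quantization <- function() {
  list(acc = 1 / 2048, gyro = 1 / 16, mag = 1 / 4, pressure = 1 / 64, t = 1e-3)
}

.int16_chan_lsb <- function() {
  q <- packet_quantization()
  rep(rep(c(q$acc, q$gyro, q$mag), each = 3), N_IMUS)
}

#' Encode one sensor frame into a wire packet
#'
#' @param frame one-row data.frame (a row of a session's frame table); the
#'   `pressure` column may be absent
#' @param seq packet sequence number (non-negative integer); consecutive
#'   frames of a stream get consecutive numbers
#' @return a `glove_packet`: list with `seq` and a 354-byte raw `payload`
#' @export
encode_packet <- function(frame, seq = 0L) {
  frame <- as.list(frame)
  chan <- channel_names(FALSE)[-1]
  vals <- unlist(frame[chan], use.names = FALSE)
  if (length(vals) != 9L * N_IMUS)
    stop("frame must carry all ", 9L * N_IMUS, " IMU channels")
  bad <- !is.finite(c(frame$t, vals))
  if (any(bad)) {
    names_all <- c("t", chan)
    stop("non-finite reading in channel(s): ",
         paste(names_all[bad], collapse = ", "))
  }
  lsb <- .int16_chan_lsb()
  ticks <- round(vals / lsb)
  if (any(abs(ticks) > 32767))
    stop("reading out of 16-bit range in channel(s): ",
         paste(chan[abs(ticks) > 32767], collapse = ", "))
  p <- frame$pressure
  p_ticks <- if (is.null(p) || is.na(p)) NA_integer_
             else as.integer(round(p / packet_quantization()$pressure))
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.integer(seq), con, size = 4, endian = "little")
  writeBin(as.integer(round(frame$t * 1000)), con, size = 4, endian = "little")
  writeBin(as.integer(ticks), con, size = 2, endian = "little")
  # NA_integer_ encodes as INT_MIN (0x80000000), the pressure-absent sentinel
  writeBin(if (is.na(p_ticks)) NA_integer_ else p_ticks,
           con, size = 4, endian = "little")
  payload <- rawConnectionValue(con)
  stopifnot(length(payload) == PACKET_BYTES)
  structure(list(seq = as.integer(seq), payload = payload),
            class = "glove_packet")
}

#' Decode a wire packet back into a sensor frame
#'
#' Inverse of [encode_packet()]: exact for values on the quantisation grid of
#' [packet_quantization()].
#' @param packet a `glove_packet`
#' @return one-row data.frame with `t`, the 171 IMU channels and, when the
#'   packet carries one, `pressure`
#' @export
decode_packet <- function(packet) {
  stopifnot(inherits(packet, "glove_packet"),
            length(packet$payload) == PACKET_BYTES)
  con <- rawConnection(packet$payload, "rb")
  on.exit(close(con))
  seq <- readBin(con, "integer", size = 4, endian = "little")
  t_ms <- readBin(con, "integer", size = 4, endian = "little")
  ticks <- readBin(con, "integer", n = 9L * N_IMUS, size = 2,
                   signed = TRUE, endian = "little")
  p_ticks <- readBin(con, "integer", size = 4, endian = "little")
  q <- packet_quantization()
  vals <- ticks * .int16_chan_lsb()
  out <- as.data.frame(as.list(stats::setNames(vals, channel_names(FALSE)[-1])))
  out <- cbind(t = t_ms * q$t, out)
  if (!is.na(p_ticks))
    out$pressure <- p_ticks * packet_quantization()$pressure
  out
}

#' Encode a whole session as a packet stream
#'
#' @param session a `glove_session`
#' @return list of `glove_packet`, with `seq` running 0, 1, 2, ...
#' @export
encode_stream <- function(session) {
  n <- nrow(session$frames)
  lapply(seq_len(n), function(i)
    encode_packet(session$frames[i, , drop = FALSE], seq = i - 1L))
}
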