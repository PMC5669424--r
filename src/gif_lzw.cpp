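// Minimal GIF87a encoder with LZW compression.
//
// This is the pinned GIF encoder used for all compression-ratio
// predictors: a global grayscale palette, a single image block, variable
// width LZW codes (LSB-first packing), dictionary reset at 4096 codes.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

namespace {

struct BitPacker {
  std::vector<uint8_t> bytes;
  uint32_t cur = 0;
  int nbits = 0;
  void push(uint32_t code, int width) {
    cur |= code << nbits;
    nbits += width;
    while (nbits >= 8) {
      bytes.push_back(static_cast<uint8_t>(cur & 0xFF));
      cur >>= 8;
      nbits -= 8;
    }
  }
  void flush() {
    if (nbits > 0) {
      bytes.push_back(static_cast<uint8_t>(cur & 0xFF));
      cur = 0;
      nbits = 0;
    }
  }
};

void put_u16(std::vector<uint8_t>& out, uint16_t v) {
  out.push_back(v & 0xFF);
  out.push_back((v >> 8) & 0xFF);
}

}  // namespace

// [[Rcpp::export]]
RawVector gif_encode_cpp(IntegerVector pixels, int width, int height,
                         int n_colors) {
  if (n_colors < 2 || n_colors > 256)
    stop("n_colors must be in [2, 256]");
  if ((int)pixels.size() != width * height)
    stop("pixel vector does not match dimensions");

  // palette bits (GCT size), at least 2 entries
  int bits = 1;
  while ((1 << bits) < n_colors) ++bits;
  int pal_size = 1 << bits;

  std::vector<uint8_t> out;
  // Header + logical screen descriptor
  const char* sig = "GIF87a";
  out.insert(out.end(), sig, sig + 6);
  put_u16(out, static_cast<uint16_t>(width));
  put_u16(out, static_cast<uint16_t>(height));
  out.push_back(static_cast<uint8_t>(0x80 | ((bits - 1) << 4) | (bits - 1)));
  out.push_back(0);  // background colour index
  out.push_back(0);  // aspect ratio
  // Global colour table: evenly spaced gray ramp
  for (int i = 0; i < pal_size; ++i) {
    uint8_t g = pal_size == 1 ? 0
        : static_cast<uint8_t>((255 * i) / (pal_size - 1));
    out.push_back(g); out.push_back(g); out.push_back(g);
  }
  // Image descriptor
  out.push_back(0x2C);
  put_u16(out, 0); put_u16(out, 0);
  put_u16(out, static_cast<uint16_t>(width));
  put_u16(out, static_cast<uint16_t>(height));
  out.push_back(0);  // no local colour table, not interlaced

  // LZW compression
  int min_code_size = bits < 2 ? 2 : bits;
  out.push_back(static_cast<uint8_t>(min_code_size));

  const uint32_t clear_code = 1u << min_code_size;
  const uint32_t eoi_code = clear_code + 1;

  BitPacker bp;
  std::unordered_map<uint64_t, uint32_t> dict;
  uint32_t next_code = eoi_code + 1;
  int code_width = min_code_size + 1;

  auto reset_dict = [&]() {
    dict.clear();
    next_code = eoi_code + 1;
    code_width = min_code_size + 1;
  };

  bp.push(clear_code, code_width);
  reset_dict();

  int n = width * height;
  // validate pixel range
  for (int i = 0; i < n; ++i)
    if (pixels[i] < 0 || pixels[i] >= n_colors)
      stop("pixel index out of palette range");

  uint32_t prefix = static_cast<uint32_t>(pixels[0]);
  for (int i = 1; i < n; ++i) {
    uint32_t k = static_cast<uint32_t>(pixels[i]);
    uint64_t key = (static_cast<uint64_t>(prefix) << 8) | k;
    auto it = dict.find(key);
    if (it != dict.end()) {
      prefix = it->second;
    } else {
      bp.push(prefix, code_width);
      if (next_code < 4096) {
        dict[key] = next_code++;
        // classic LZW rule: widen once the next free slot no longer fits
        if (next_code > (1u << code_width) && code_width < 12)
          ++code_width;
      } else {
        bp.push(clear_code, code_width);
        reset_dict();
      }
      prefix = k;
    }
  }
  bp.push(prefix, code_width);
  bp.push(eoi_code, code_width);
  bp.flush();

  // data sub-blocks of at most 255 bytes
  size_t pos = 0;
  while (pos < bp.bytes.size()) {
    size_t len = std::min<size_t>(255, bp.bytes.size() - pos);
    out.push_back(static_cast<uint8_t>(len));
    out.insert(out.end(), bp.bytes.begin() + pos, bp.bytes.begin() + pos + len);
    pos += len;
  }
  out.push_back(0);     // block terminator
  out.push_back(0x3B);  // trailer

  RawVector res(out.size());
  std::copy(out.begin(), out.end(), res.begin());
  return res;
}
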