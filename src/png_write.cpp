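// Minimal grayscale PNG encoder (8- and 16-bit, colour type 0).
//
// The CRAN `png` package reads 16-bit PNGs but only writes 8-bit ones, so
// depth clips stored at full Kinect-style precision need this writer.
// Scanlines use filter type 0 and a single zlib stream (compress2).

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <vector>

using namespace Rcpp;

static void push_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff); v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);  v.push_back(x & 0xff);
}

static void write_chunk(FILE* f, const char type[4],
                        const unsigned char* data, uint32_t len) {
  std::vector<unsigned char> head;
  push_u32(head, len);
  fwrite(head.data(), 1, 4, f);
  fwrite(type, 1, 4, f);
  if (len) fwrite(data, 1, len, f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*)type, 4);
  if (len) crc = crc32(crc, data, len);
  std::vector<unsigned char> tail;
  push_u32(tail, (uint32_t)crc);
  fwrite(tail.data(), 1, 4, f);
}

// m: integer matrix (H x W), values in [0, 2^bit_depth - 1], row i = scanline i.
// [[Rcpp::export(name = ".write_png_gray_cpp")]]
void write_png_gray_cpp(IntegerMatrix m, std::string path, int bit_depth) {
  if (bit_depth != 8 && bit_depth != 16) stop("bit_depth must be 8 or 16");
  int H = m.nrow(), W = m.ncol();
  int bpp = bit_depth / 8;
  size_t stride = (size_t)W * bpp + 1;  // +1 filter byte
  std::vector<unsigned char> raw(stride * H);
  for (int i = 0; i < H; ++i) {
    unsigned char* row = raw.data() + stride * i;
    row[0] = 0;  // filter: none
    for (int j = 0; j < W; ++j) {
      int v = m(i, j);
      if (v < 0) v = 0;
      int vmax = (bit_depth == 8) ? 255 : 65535;
      if (v > vmax) v = vmax;
      if (bit_depth == 8) row[1 + j] = (unsigned char)v;
      else { row[1 + 2 * j] = (v >> 8) & 0xff; row[2 + 2 * j] = v & 0xff; }
    }
  }
  uLongf clen = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("PNG write: zlib compression failed");

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("PNG write: cannot open '%s'", path.c_str());
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  push_u32(ihdr, (uint32_t)W);
  push_u32(ihdr, (uint32_t)H);
  ihdr.push_back((unsigned char)bit_depth);
  ihdr.push_back(0);  // colour type: grayscale
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  write_chunk(f, "IHDR", ihdr.data(), (uint32_t)ihdr.size());
  write_chunk(f, "IDAT", comp.data(), (uint32_t)clen);
  write_chunk(f, "IEND", nullptr, 0);
  std::fclose(f);
}
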