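// Minimal grayscale/RGB PNG and baseline TIFF codecs.
// No image-I/O library is available at build time, so the two lossless
// containers the package needs are implemented directly on top of zlib.
// PNG: bit depths 8/16, colour types 0/2/4/6, no interlacing, no palette.
// TIFF: uncompressed baseline grayscale, 8/16 bit, either byte order on read.
#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>

using namespace Rcpp;

static std::vector<unsigned char> read_file_bytes(const std::string& path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open file '%s'", path.c_str());
  std::fseek(f, 0, SEEK_END);
  long n = std::ftell(f);
  std::fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf(n > 0 ? (size_t)n : 0);
  if (n > 0 && std::fread(buf.data(), 1, (size_t)n, f) != (size_t)n) {
    std::fclose(f);
    stop("short read on '%s'", path.c_str());
  }
  std::fclose(f);
  return buf;
}

static void write_file_bytes(const std::string& path,
                             const std::vector<unsigned char>& buf) {
  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open file '%s' for writing", path.c_str());
  if (!buf.empty() && std::fwrite(buf.data(), 1, buf.size(), f) != buf.size()) {
    std::fclose(f);
    stop("short write on '%s'", path.c_str());
  }
  std::fclose(f);
}

static inline void push_u32be(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff); v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);  v.push_back(x & 0xff);
}

static inline uint32_t get_u32be(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void png_chunk(std::vector<unsigned char>& out, const char* type,
                      const std::vector<unsigned char>& data) {
  push_u32be(out, (uint32_t)data.size());
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  out.insert(out.end(), data.begin(), data.end());
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(4 + data.size()));
  push_u32be(out, (uint32_t)crc);
}

// [[Rcpp::export(name = ".png_write_gray")]]
void png_write_gray_cpp(std::string path, IntegerMatrix pixels, int bit_depth) {
  if (bit_depth != 8 && bit_depth != 16) stop("PNG bit depth must be 8 or 16");
  int H = pixels.nrow(), W = pixels.ncol();
  int maxval = (bit_depth == 8) ? 255 : 65535;
  int bpp = bit_depth / 8;
  size_t stride = (size_t)W * bpp + 1;
  std::vector<unsigned char> raw((size_t)H * stride);
  for (int h = 0; h < H; ++h) {
    unsigned char* row = raw.data() + (size_t)h * stride;
    row[0] = 0;  // filter type None
    for (int w = 0; w < W; ++w) {
      int v = pixels(h, w);
      if (v < 0 || v > maxval) stop("pixel value %d out of range for %d-bit PNG", v, bit_depth);
      if (bpp == 1) row[1 + w] = (unsigned char)v;
      else { row[1 + 2 * w] = (v >> 8) & 0xff; row[2 + 2 * w] = v & 0xff; }
    }
  }
  uLongf comp_len = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(comp_len);
  if (compress2(comp.data(), &comp_len, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("zlib compression failed");
  comp.resize(comp_len);

  std::vector<unsigned char> out;
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  out.insert(out.end(), sig, sig + 8);
  std::vector<unsigned char> ihdr;
  push_u32be(ihdr, (uint32_t)W);
  push_u32be(ihdr, (uint32_t)H);
  ihdr.push_back((unsigned char)bit_depth);
  ihdr.push_back(0);  // grayscale
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  png_chunk(out, "IHDR", ihdr);
  png_chunk(out, "IDAT", comp);
  png_chunk(out, "IEND", std::vector<unsigned char>());
  write_file_bytes(path, out);
}

static inline int paeth(int a, int b, int c) {
  int p = a + b - c, pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export(name = ".png_read")]]
List png_read_cpp(std::string path) {
  std::vector<unsigned char> buf = read_file_bytes(path);
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  if (buf.size() < 8 || std::memcmp(buf.data(), sig, 8) != 0)
    stop("'%s' is not a PNG file", path.c_str());
  size_t pos = 8;
  uint32_t W = 0, H = 0;
  int bit_depth = 0, color_type = 0, interlace = 0;
  std::vector<unsigned char> idat;
  bool seen_ihdr = false;
  while (pos + 8 <= buf.size()) {
    uint32_t len = get_u32be(buf.data() + pos);
    if (pos + 12 + (size_t)len > buf.size()) stop("corrupt PNG chunk in '%s'", path.c_str());
    const char* type = (const char*)buf.data() + pos + 4;
    const unsigned char* data = buf.data() + pos + 8;
    if (std::memcmp(type, "IHDR", 4) == 0) {
      if (len != 13) stop("corrupt IHDR");
      W = get_u32be(data); H = get_u32be(data + 4);
      bit_depth = data[8]; color_type = data[9]; interlace = data[12];
      seen_ihdr = true;
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), data, data + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      break;
    }
    pos += 12 + len;
  }
  if (!seen_ihdr || W == 0 || H == 0) stop("corrupt PNG: missing IHDR");
  if (interlace != 0) stop("interlaced PNG not supported");
  if (bit_depth != 8 && bit_depth != 16)
    stop("unsupported PNG bit depth %d (only 8/16)", bit_depth);
  int channels;
  switch (color_type) {
    case 0: channels = 1; break;
    case 2: channels = 3; break;
    case 4: channels = 2; break;
    case 6: channels = 4; break;
    default: stop("unsupported PNG colour type %d (palette images not supported)", color_type);
  }
  int bytes_per_sample = bit_depth / 8;
  size_t bpp = (size_t)channels * bytes_per_sample;
  size_t stride = (size_t)W * bpp + 1;
  uLongf raw_len = (uLongf)((size_t)H * stride);
  std::vector<unsigned char> raw(raw_len);
  int zret = uncompress(raw.data(), &raw_len, idat.data(), (uLong)idat.size());
  if (zret != Z_OK || raw_len != (uLongf)((size_t)H * stride))
    stop("PNG decompression failed (zlib code %d)", zret);

  // undo scanline filters in place (payload shifted out of the filter byte)
  std::vector<unsigned char> img((size_t)H * W * bpp);
  for (uint32_t h = 0; h < H; ++h) {
    unsigned char ft = raw[(size_t)h * stride];
    const unsigned char* src = raw.data() + (size_t)h * stride + 1;
    unsigned char* cur = img.data() + (size_t)h * W * bpp;
    const unsigned char* prev = (h == 0) ? NULL : img.data() + (size_t)(h - 1) * W * bpp;
    size_t rowlen = (size_t)W * bpp;
    for (size_t i = 0; i < rowlen; ++i) {
      int a = (i >= bpp) ? cur[i - bpp] : 0;
      int b = prev ? prev[i] : 0;
      int c = (prev && i >= bpp) ? prev[i - bpp] : 0;
      int x = src[i];
      switch (ft) {
        case 0: break;
        case 1: x = (x + a) & 0xff; break;
        case 2: x = (x + b) & 0xff; break;
        case 3: x = (x + (a + b) / 2) & 0xff; break;
        case 4: x = (x + paeth(a, b, c)) & 0xff; break;
        default: stop("unsupported PNG filter type %d", (int)ft);
      }
      cur[i] = (unsigned char)x;
    }
  }

  int keep = (channels >= 3) ? 3 : 1;  // drop alpha
  NumericVector px((R_xlen_t)H * W * keep);
  for (uint32_t h = 0; h < H; ++h) {
    for (uint32_t w = 0; w < W; ++w) {
      const unsigned char* p = img.data() + ((size_t)h * W + w) * bpp;
      for (int k = 0; k < keep; ++k) {
        int v;
        if (bytes_per_sample == 1) v = p[k];
        else v = ((int)p[2 * k] << 8) | p[2 * k + 1];
        px[(R_xlen_t)h + (R_xlen_t)H * w + (R_xlen_t)H * W * k] = v;
      }
    }
  }
  px.attr("dim") = IntegerVector::create((int)H, (int)W, keep);
  return List::create(_["pixels"] = px, _["bit_depth"] = bit_depth,
                      _["channels"] = keep);
}

// --- baseline TIFF, uncompressed grayscale ---

static inline void push_u16le(std::vector<unsigned char>& v, uint16_t x) {
  v.push_back(x & 0xff); v.push_back((x >> 8) & 0xff);
}
static inline void push_u32le(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back(x & 0xff); v.push_back((x >> 8) & 0xff);
  v.push_back((x >> 16) & 0xff); v.push_back((x >> 24) & 0xff);
}

static void tiff_tag(std::vector<unsigned char>& ifd, uint16_t tag,
                     uint16_t type, uint32_t count, uint32_t value) {
  push_u16le(ifd, tag); push_u16le(ifd, type); push_u32le(ifd, count);
  if (type == 3 && count == 1) { push_u16le(ifd, (uint16_t)value); push_u16le(ifd, 0); }
  else push_u32le(ifd, value);
}

// [[Rcpp::export(name = ".tiff_write_gray")]]
void tiff_write_gray_cpp(std::string path, IntegerMatrix pixels, int bit_depth) {
  if (bit_depth != 8 && bit_depth != 16) stop("TIFF bit depth must be 8 or 16");
  int H = pixels.nrow(), W = pixels.ncol();
  int maxval = (bit_depth == 8) ? 255 : 65535;
  std::vector<unsigned char> out;
  out.push_back('I'); out.push_back('I'); push_u16le(out, 42);
  size_t data_bytes = (size_t)H * W * (bit_depth / 8);
  uint32_t strip_offset = 8;
  uint32_t ifd_offset = (uint32_t)(8 + data_bytes);
  push_u32le(out, ifd_offset);
  for (int h = 0; h < H; ++h)
    for (int w = 0; w < W; ++w) {
      int v = pixels(h, w);
      if (v < 0 || v > maxval) stop("pixel value %d out of range for %d-bit TIFF", v, bit_depth);
      if (bit_depth == 8) out.push_back((unsigned char)v);
      else push_u16le(out, (uint16_t)v);
    }
  std::vector<unsigned char> ifd;
  push_u16le(ifd, 8);  // number of tags
  tiff_tag(ifd, 256, 4, 1, (uint32_t)W);             // ImageWidth
  tiff_tag(ifd, 257, 4, 1, (uint32_t)H);             // ImageLength
  tiff_tag(ifd, 258, 3, 1, (uint32_t)bit_depth);     // BitsPerSample
  tiff_tag(ifd, 259, 3, 1, 1);                       // Compression: none
  tiff_tag(ifd, 262, 3, 1, 1);                       // Photometric: BlackIsZero
  tiff_tag(ifd, 273, 4, 1, strip_offset);            // StripOffsets
  tiff_tag(ifd, 278, 4, 1, (uint32_t)H);             // RowsPerStrip
  tiff_tag(ifd, 279, 4, 1, (uint32_t)data_bytes);    // StripByteCounts
  push_u32le(ifd, 0);  // next IFD
  out.insert(out.end(), ifd.begin(), ifd.end());
  write_file_bytes(path, out);
}

struct TiffReader {
  const unsigned char* p; size_t n; bool le;
  uint16_t u16(size_t off) const {
    if (off + 2 > n) stop("corrupt TIFF");
    return le ? (p[off] | (p[off + 1] << 8)) : ((p[off] << 8) | p[off + 1]);
  }
  uint32_t u32(size_t off) const {
    if (off + 4 > n) stop("corrupt TIFF");
    return le ? ((uint32_t)p[off] | ((uint32_t)p[off+1] << 8) | ((uint32_t)p[off+2] << 16) | ((uint32_t)p[off+3] << 24))
              : (((uint32_t)p[off] << 24) | ((uint32_t)p[off+1] << 16) | ((uint32_t)p[off+2] << 8) | (uint32_t)p[off+3]);
  }
};

// [[Rcpp::export(name = ".tiff_read_gray")]]
List tiff_read_gray_cpp(std::string path) {
  std::vector<unsigned char> buf = read_file_bytes(path);
  if (buf.size() < 8) stop("'%s' is not a TIFF file", path.c_str());
  TiffReader rd; rd.p = buf.data(); rd.n = buf.size();
  if (buf[0] == 'I' && buf[1] == 'I') rd.le = true;
  else if (buf[0] == 'M' && buf[1] == 'M') rd.le = false;
  else stop("'%s' is not a TIFF file", path.c_str());
  if (rd.u16(2) != 42) stop("'%s' is not a TIFF file", path.c_str());
  uint32_t ifd = rd.u32(4);
  uint16_t ntags = rd.u16(ifd);
  uint32_t W = 0, H = 0, bits = 1, comp = 1, photo = 1, spp = 1, rps = 0xffffffff;
  std::vector<uint32_t> strip_offsets, strip_counts;
  for (uint16_t t = 0; t < ntags; ++t) {
    size_t off = ifd + 2 + (size_t)t * 12;
    uint16_t tag = rd.u16(off), type = rd.u16(off + 2);
    uint32_t count = rd.u32(off + 4);
    uint32_t val = (type == 3) ? rd.u16(off + 8) : rd.u32(off + 8);
    switch (tag) {
      case 256: W = val; break;
      case 257: H = val; break;
      case 258: bits = (count == 1) ? val : rd.u16(rd.u32(off + 8)); break;
      case 259: comp = val; break;
      case 262: photo = val; break;
      case 277: spp = val; break;
      case 278: rps = val; break;
      case 273: case 279: {
        std::vector<uint32_t>& dst = (tag == 273) ? strip_offsets : strip_counts;
        if (count == 1) dst.push_back(val);
        else {
          uint32_t base = rd.u32(off + 8);
          for (uint32_t i = 0; i < count; ++i)
            dst.push_back(type == 3 ? rd.u16(base + 2 * i) : rd.u32(base + 4 * i));
        }
        break;
      }
      default: break;
    }
  }
  if (comp != 1) stop("only uncompressed TIFF is supported");
  if (spp != 1) stop("only single-sample (grayscale) TIFF is supported");
  if (bits != 8 && bits != 16) stop("unsupported TIFF bit depth %u", bits);
  if (W == 0 || H == 0 || strip_offsets.empty()) stop("corrupt TIFF: no image data");
  int bps = bits / 8;
  NumericMatrix px((int)H, (int)W);
  size_t row = 0;
  uint32_t rows_per_strip = (rps == 0xffffffff) ? H : rps;
  for (size_t s = 0; s < strip_offsets.size() && row < H; ++s) {
    size_t off = strip_offsets[s];
    for (uint32_t r = 0; r < rows_per_strip && row < H; ++r, ++row) {
      for (uint32_t w = 0; w < W; ++w) {
        size_t so = off + ((size_t)r * W + w) * bps;
        int v = (bps == 1) ? rd.p[so]
                           : (rd.le ? (rd.p[so] | (rd.p[so + 1] << 8))
                                    : ((rd.p[so] << 8) | rd.p[so + 1]));
        if (photo == 0) v = ((1 << bits) - 1) - v;  // WhiteIsZero
        px(row, w) = v;
      }
    }
  }
  return List::create(_["pixels"] = px, _["bit_depth"] = (int)bits);
}
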