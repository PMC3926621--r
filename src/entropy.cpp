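// Bit-exact entropy coders: canonical Huffman (with escape symbol) and an
// adaptive order-0 arithmetic coder.  Bitstreams use big-endian bit order
// within each byte (MSB first).

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct BitWriter {
  std::vector<uint8_t> bytes;
  int nbits = 0;
  void put(int bit) {
    if ((nbits & 7) == 0) bytes.push_back(0);
    if (bit) bytes.back() |= static_cast<uint8_t>(0x80u >> (nbits & 7));
    ++nbits;
  }
  void put_code(uint64_t code, int len) {
    for (int b = len - 1; b >= 0; --b) put(static_cast<int>((code >> b) & 1u));
  }
};

struct BitReader {
  const uint8_t* bytes;
  long long nbits;   // valid bit count
  long long pos = 0;
  BitReader(const uint8_t* b, long long n) : bytes(b), nbits(n) {}
  bool exhausted() const { return pos >= nbits; }
  int get() {
    if (pos >= nbits) { ++pos; return 0; }  // caller checks overrun
    int bit = (bytes[pos >> 3] >> (7 - (pos & 7))) & 1;
    ++pos;
    return bit;
  }
};

// Canonical code construction from (symbol, length) pairs already sorted
// by (length, symbol) on the R side.
void canonical_codes(const IntegerVector& lens, std::vector<uint64_t>& codes) {
  int n = lens.size();
  codes.resize(n);
  uint64_t code = 0;
  int prev = lens[0];
  for (int k = 0; k < n; ++k) {
    code <<= (lens[k] - prev);
    prev = lens[k];
    codes[k] = code;
    ++code;
  }
}

}  // namespace

// [[Rcpp::export]]
List huffman_encode_cpp(IntegerVector input, IntegerVector cb_syms,
                        IntegerVector cb_lens, int esc_sym, int raw_bits) {
  std::vector<uint64_t> codes;
  canonical_codes(cb_lens, codes);
  std::unordered_map<int, int> slot;
  slot.reserve(cb_syms.size() * 2);
  for (int k = 0; k < cb_syms.size(); ++k) slot[cb_syms[k]] = k;
  auto esc_it = slot.find(esc_sym);
  BitWriter bw;
  IntegerVector pos(input.size());
  for (int t = 0; t < input.size(); ++t) {
    pos[t] = bw.nbits;
    auto it = slot.find(input[t]);
    if (it != slot.end()) {
      bw.put_code(codes[it->second], cb_lens[it->second]);
    } else {
      if (esc_it == slot.end())
        stop("symbol %d not in codebook and no escape symbol", input[t]);
      bw.put_code(codes[esc_it->second], cb_lens[esc_it->second]);
      bw.put_code(static_cast<uint64_t>(input[t]), raw_bits);
    }
  }
  RawVector out(bw.bytes.size());
  std::copy(bw.bytes.begin(), bw.bytes.end(), out.begin());
  return List::create(_["bytes"] = out, _["nbits"] = bw.nbits,
                      _["sym_bitpos"] = pos);
}

// [[Rcpp::export]]
IntegerVector huffman_decode_cpp(RawVector bytes, double total_bits,
                                 double start_bit, int n_symbols,
                                 IntegerVector cb_syms, IntegerVector cb_lens,
                                 int esc_sym, int raw_bits) {
  std::vector<uint64_t> codes;
  canonical_codes(cb_lens, codes);
  int n = cb_syms.size();
  int lmax = cb_lens[n - 1];
  // per-length tables for canonical decode
  std::vector<uint64_t> first_code(lmax + 1, 0);
  std::vector<int> first_idx(lmax + 1, 0), count(lmax + 1, 0);
  for (int k = 0; k < n; ++k) {
    int l = cb_lens[k];
    if (count[l] == 0) { first_code[l] = codes[k]; first_idx[l] = k; }
    ++count[l];
  }
  BitReader br(RAW(bytes), static_cast<long long>(total_bits));
  br.pos = static_cast<long long>(start_bit);
  IntegerVector out(n_symbols);
  for (int t = 0; t < n_symbols; ++t) {
    uint64_t acc = 0;
    int l = 0;
    int sym;
    for (;;) {
      if (br.exhausted())
        stop("truncated bitstream at symbol %d", t + 1);
      acc = (acc << 1) | static_cast<uint64_t>(br.get());
      ++l;
      if (l > lmax) stop("invalid bitstream at symbol %d", t + 1);
      if (count[l] > 0 && acc >= first_code[l] &&
          acc < first_code[l] + static_cast<uint64_t>(count[l])) {
        sym = cb_syms[first_idx[l] + static_cast<int>(acc - first_code[l])];
        break;
      }
    }
    if (sym == esc_sym) {
      uint64_t v = 0;
      for (int b = 0; b < raw_bits; ++b) {
        if (br.exhausted()) stop("truncated bitstream at symbol %d", t + 1);
        v = (v << 1) | static_cast<uint64_t>(br.get());
      }
      sym = static_cast<int>(v);
    }
    out[t] = sym;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Adaptive arithmetic coder (Witten-Neal-Cleary style, 32-bit registers).
// Order-0 model over a fixed alphabet, counts start at 1 and are halved
// (keeping a floor of 1) when the total reaches MAX_TOTAL.

namespace {

constexpr uint32_t TOP = 0xFFFFFFFFu;
constexpr uint32_t HALF = 0x80000000u;
constexpr uint32_t QTR = 0x40000000u;
constexpr uint32_t MAX_TOTAL = 1u << 15;

struct Model {
  std::vector<uint32_t> freq;
  uint32_t total;
  explicit Model(int alpha) : freq(alpha, 1), total(alpha) {}
  void cum(int sym, uint32_t& lo, uint32_t& hi) const {
    uint32_t c = 0;
    for (int k = 0; k < sym; ++k) c += freq[k];
    lo = c;
    hi = c + freq[sym];
  }
  int find(uint32_t target, uint32_t& lo, uint32_t& hi) const {
    uint32_t c = 0;
    for (size_t k = 0; k < freq.size(); ++k) {
      if (target < c + freq[k]) {
        lo = c; hi = c + freq[k];
        return static_cast<int>(k);
      }
      c += freq[k];
    }
    return -1;
  }
  void update(int sym) {
    freq[sym] += 32;
    total += 32;
    if (total >= MAX_TOTAL) {
      total = 0;
      for (auto& f : freq) { f = (f + 1) >> 1; total += f; }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List arith_encode_cpp(IntegerVector input, int alpha) {
  Model m(alpha);
  BitWriter bw;
  uint32_t low = 0, high = TOP;
  long long pending = 0;
  auto emit = [&](int bit) {
    bw.put(bit);
    while (pending > 0) { bw.put(!bit); --pending; }
  };
  for (int t = 0; t < input.size(); ++t) {
    int sym = input[t];
    if (sym < 0 || sym >= alpha) stop("symbol out of alphabet");
    uint32_t clo, chi;
    m.cum(sym, clo, chi);
    uint64_t range = static_cast<uint64_t>(high) - low + 1;
    high = low + static_cast<uint32_t>(range * chi / m.total - 1);
    low  = low + static_cast<uint32_t>(range * clo / m.total);
    for (;;) {
      if (high < HALF) {
        emit(0);
      } else if (low >= HALF) {
        emit(1); low -= HALF; high -= HALF;
      } else if (low >= QTR && high < HALF + QTR) {
        ++pending; low -= QTR; high -= QTR;
      } else break;
      low <<= 1;
      high = (high << 1) | 1;
    }
    m.update(sym);
  }
  // flush: one disambiguating bit plus pending
  ++pending;
  if (low < QTR) emit(0); else emit(1);
  RawVector out(bw.bytes.size());
  std::copy(bw.bytes.begin(), bw.bytes.end(), out.begin());
  return List::create(_["bytes"] = out, _["nbits"] = bw.nbits);
}

// [[Rcpp::export]]
IntegerVector arith_decode_cpp(RawVector bytes, double total_bits,
                               int n_symbols, int alpha) {
  Model m(alpha);
  long long nbits = static_cast<long long>(total_bits);
  BitReader br(RAW(bytes), nbits);
  uint32_t low = 0, high = TOP, value = 0;
  for (int b = 0; b < 32; ++b) value = (value << 1) | static_cast<uint32_t>(br.get());
  IntegerVector out(n_symbols);
  for (int t = 0; t < n_symbols; ++t) {
    uint64_t range = static_cast<uint64_t>(high) - low + 1;
    uint32_t target =
        static_cast<uint32_t>(((static_cast<uint64_t>(value - low) + 1) * m.total - 1) / range);
    uint32_t clo, chi;
    int sym = m.find(target, clo, chi);
    if (sym < 0) stop("corrupt arithmetic stream at symbol %d", t + 1);
    out[t] = sym;
    high = low + static_cast<uint32_t>(range * chi / m.total - 1);
    low  = low + static_cast<uint32_t>(range * clo / m.total);
    for (;;) {
      if (high < HALF) {
        // nothing
      } else if (low >= HALF) {
        low -= HALF; high -= HALF; value -= HALF;
      } else if (low >= QTR && high < HALF + QTR) {
        low -= QTR; high -= QTR; value -= QTR;
      } else break;
      low <<= 1;
      high = (high << 1) | 1;
      value = (value << 1) | static_cast<uint32_t>(br.get());
      if (br.pos > nbits + 48)
        stop("truncated arithmetic stream at symbol %d", t + 1);
    }
    m.update(sym);
  }
  return out;
}
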