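#ifndef UHSKIT_BIGNUM_H
#define UHSKIT_BIGNUM_H

#include <vector>
#include <string>
#include <cstdint>
#include <cstdio>
#include <algorithm>

// Exact non-negative integers for path counts. Counts of l-edge paths grow
// like sigma^l and overflow both 64-bit integers and the 2^53 exact range of
// doubles well inside the parameter range this package supports, so counts
// are kept in arbitrary precision throughout.
struct Big {
    std::vector<uint32_t> d; // little-endian limbs, base 2^32; empty == 0

    Big() {}
    explicit Big(uint64_t v) {
        if (v) {
            d.push_back(static_cast<uint32_t>(v));
            if (v >> 32) d.push_back(static_cast<uint32_t>(v >> 32));
        }
    }
    bool zero() const { return d.empty(); }
    void clear() { d.clear(); }
    void trim() { while (!d.empty() && d.back() == 0) d.pop_back(); }

    void add(const Big &o) {
        const size_t n = std::max(d.size(), o.d.size());
        d.resize(n, 0u);
        uint64_t carry = 0;
        for (size_t i = 0; i < n; ++i) {
            uint64_t s = carry + d[i] + (i < o.d.size() ? o.d[i] : 0u);
            d[i] = static_cast<uint32_t>(s);
            carry = s >> 32;
        }
        if (carry) d.push_back(static_cast<uint32_t>(carry));
    }
};

inline Big big_mul(const Big &a, const Big &b) {
    Big r;
    if (a.zero() || b.zero()) return r;
    r.d.assign(a.d.size() + b.d.size(), 0u);
    for (size_t i = 0; i < a.d.size(); ++i) {
        uint64_t carry = 0;
        for (size_t j = 0; j < b.d.size(); ++j) {
            uint64_t cur = r.d[i + j] + static_cast<uint64_t>(a.d[i]) * b.d[j] + carry;
            r.d[i + j] = static_cast<uint32_t>(cur);
            carry = cur >> 32;
        }
        size_t j = b.d.size();
        while (carry) {
            uint64_t cur = r.d[i + j] + carry;
            r.d[i + j] = static_cast<uint32_t>(cur);
            carry = cur >> 32;
            ++j;
        }
    }
    r.trim();
    return r;
}

// -1, 0, 1 as a < b, a == b, a > b
inline int big_cmp(const Big &a, const Big &b) {
    if (a.d.size() != b.d.size()) return a.d.size() < b.d.size() ? -1 : 1;
    for (size_t i = a.d.size(); i-- > 0;) {
        if (a.d[i] != b.d[i]) return a.d[i] < b.d[i] ? -1 : 1;
    }
    return 0;
}

inline std::string big_dec(Big a) { // by value: destroyed by repeated division
    if (a.zero()) return "0";
    std::string out;
    while (!a.zero()) {
        uint64_t rem = 0;
        for (size_t i = a.d.size(); i-- > 0;) {
            uint64_t cur = (rem << 32) | a.d[i];
            a.d[i] = static_cast<uint32_t>(cur / 1000000000ULL);
            rem = cur % 1000000000ULL;
        }
        a.trim();
        char buf[16];
        if (a.zero())
            snprintf(buf, sizeof buf, "%llu", static_cast<unsigned long long>(rem));
        else
            snprintf(buf, sizeof buf, "%09llu", static_cast<unsigned long long>(rem));
        out = std::string(buf) + out;
    }
    return out;
}

#endif
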