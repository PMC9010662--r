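{"MeshVertex3":{"_ArrayType_":"double","_ArraySize_":[8,3],"_ArrayZipType_":"zlib","_ArrayZipSize_":[8,3],"_ArrayZipData_":"eJxjYMAHPtjjFyckT8hcdHXo4oTVAQDgMQ41"},"MeshTri3":{"_ArrayType_":"int32","_ArraySize_":[12,3],"_ArrayZipType_":"zlib","_ArrayZipSize_":[12,3],"_ArrayZipData_":"eJw1i0sWAEAEw+ozuP+JxyIWfYLUJcWmN86sTcIBD/vjf9z8jH7BSdfwzgk845Zw4X0xgACh\n"},"MeshTet4":{"_ArrayType_":"int32","_ArraySize_":[6,5],"_ArrayZipType_":"zlib","_ArrayZipSize_":[6,5],"_ArrayZipData_":"eJxjZGBgYAJiZiBmB2JGKGaC8tmQxFigYsxoYhxoelmh+tDF2KFqQXwAGMAAbw=="},"LengthUnit":"mm","Comment":"unit cube: 8 nodes, 12 surface triangles, 6 tetrahedra"}
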